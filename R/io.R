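#' Read and validate a run configuration
#'
#' The configuration is a YAML file with up to six top-level blocks:
#' `params` (any subset of the [sim_params()] fields; omitted fields take
#' their defaults), `scenario` (a [scenario()] name and/or its fields),
#' `n_generations`, `base_seed`, `output_dir` and `record_every`. Unknown
#' keys and out-of-range values raise descriptive errors.
#'
#' @param path Path to a YAML configuration file.
#' @return An object of class `pm_config`: list with `params`
#'   (`sim_params`), `scenario` (`pm_scenario`), `n_generations`,
#'   `base_seed`, `output_dir`, `record_every`.
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines("scenario:\n  name: compl-zero\nn_generations: 50", cfg_file)
#' cfg <- read_run_config(cfg_file)
#' cfg$params$K  # 100, the default
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("configuration file '%s' not found", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- c("params", "scenario", "n_generations", "base_seed",
               "output_dir", "record_every")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  par_block <- raw$params
  if (!is.null(par_block)) {
    bad <- setdiff(names(par_block), names(formals(sim_params)))
    if (length(bad))
      stop("unknown parameter keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  params <- do.call(sim_params, as.list(par_block))
  sc_block <- raw$scenario
  if (!is.null(sc_block)) {
    bad <- setdiff(names(sc_block),
                   c("name", "init_region", "init_diversity", "change",
                     "change_generation", "n_replicates"))
    if (length(bad))
      stop("unknown scenario keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  sc <- do.call(scenario, as.list(sc_block))
  cfg <- list(params = params, scenario = sc,
              n_generations = as.integer(raw$n_generations %||% 1000L),
              base_seed = as.integer(raw$base_seed %||% 1L),
              output_dir = raw$output_dir %||% ".",
              record_every = as.integer(raw$record_every %||% 1L))
  if (cfg$n_generations < 1L || cfg$record_every < 1L || is.na(cfg$base_seed))
    stop("'n_generations' and 'record_every' must be positive integers ",
         "and 'base_seed' an integer", call. = FALSE)
  if (sc$change != "none" && sc$change_generation > cfg$n_generations)
    stop("'change_generation' exceeds 'n_generations'", call. = FALSE)
  class(cfg) <- "pm_config"
  cfg
}

#' @rdname read_run_config
#' @param config A `pm_config` object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "pm_config"))
  out <- list(params = unclass(config$params),
              scenario = unclass(config$scenario),
              n_generations = config$n_generations,
              base_seed = config$base_seed,
              output_dir = config$output_dir,
              record_every = config$record_every)
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

CSV_SCHEMA <- "partmig csv schema v1"

#' Write and read per-replicate result tables
#'
#' `write_replicate_csv()` writes a replicate's per-generation zone table
#' to `<stem>_zone.csv` and, when the run kept it, the per-(generation, x)
#' table (migrant count, resident count, mean threshold) to
#' `<stem>_perx.csv`. Files carry a schema header comment; missing values
#' are written as empty fields. `read_replicate_csv()` reads them back
#' into a list usable by [aggregate_replicates()].
#'
#' `write_replicates()` writes one file pair per replicate of a
#' [run_replicates()] result plus the aggregate table
#' (`<scenario>_aggregate.csv`).
#'
#' @param run A `pm_run`.
#' @param stem Output path stem (directory + file prefix).
#' @return The written paths (invisibly), or for the readers the parsed
#'   tables.
#' @examples
#' p <- sim_params(x_max = 20, y_max = 2, K = 5)
#' run <- run_simulation(scenario("compl-zero"), p, n_generations = 3,
#'                       seed = 1, keep_per_x = TRUE)
#' stem <- file.path(tempdir(), "demo_rep001")
#' write_replicate_csv(run, stem)
#' nrow(read_replicate_csv(stem)$zone)
#' @export
write_replicate_csv <- function(run, stem) {
  stopifnot(inherits(run, "pm_run"))
  zpath <- paste0(stem, "_zone.csv")
  write_csv_schema(run$zone, zpath,
                   sprintf("%s; scenario=%s seed=%d", CSV_SCHEMA,
                           run$scenario$name, run$seed))
  paths <- zpath
  if (!is.null(run$per_x)) {
    xpath <- paste0(stem, "_perx.csv")
    write_csv_schema(run$per_x, xpath,
                     sprintf("%s; scenario=%s seed=%d", CSV_SCHEMA,
                             run$scenario$name, run$seed))
    paths <- c(paths, xpath)
  }
  invisible(paths)
}

#' @rdname write_replicate_csv
#' @export
read_replicate_csv <- function(stem) {
  read_num <- function(path) {
    df <- utils::read.csv(path, comment.char = "#")
    # columns that were entirely missing come back logical; all schema
    # columns are numeric
    for (j in seq_along(df))
      if (is.logical(df[[j]])) df[[j]] <- as.numeric(df[[j]])
    df
  }
  out <- list(zone = read_num(paste0(stem, "_zone.csv")))
  xpath <- paste0(stem, "_perx.csv")
  if (file.exists(xpath)) out$per_x <- read_num(xpath)
  out
}

#' @rdname write_replicate_csv
#' @param reps A `pm_replicates` object.
#' @param dir Output directory (created if needed).
#' @export
write_replicates <- function(reps, dir) {
  stopifnot(inherits(reps, "pm_replicates"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stems <- file.path(dir, sprintf("%s_rep%03d", reps$scenario$name,
                                  seq_along(reps$runs)))
  for (i in seq_along(reps$runs))
    write_replicate_csv(reps$runs[[i]], stems[i])
  agg <- aggregate_replicates(reps)
  apath <- file.path(dir, sprintf("%s_aggregate.csv", reps$scenario$name))
  write_csv_schema(as.data.frame(agg), apath,
                   sprintf("%s; aggregate over %d replicates", CSV_SCHEMA,
                           length(reps$runs)))
  invisible(c(stems, apath))
}

write_csv_schema <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, na = "",
                     qmethod = "double")
  invisible(path)
}
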