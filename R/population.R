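#' Population state
#'
#' A `pm_population` stores the whole landscape's individuals as parallel
#' vectors: patch coordinates `x`, `y` (1-based, inclusive), the heritable
#' migration threshold `threshold` in `[0, 1]`, and the current generation's
#' phenotype as a logical `resident` flag (`NA` = undecided, i.e. the
#' individual has not yet faced a winter). Newly produced offspring are
#' always undecided until the next decision step.
#'
#' @param x,y Integer vectors of patch coordinates.
#' @param threshold Numeric vector of migration thresholds in `[0, 1]`.
#' @param generation Non-negative integer generation counter.
#' @param x_max,y_max Landscape extent.
#' @param resident Logical phenotype flags (`TRUE` resident, `FALSE`
#'   migrant, `NA` undecided).
#'
#' @return An object of class `pm_population`.
#' @examples
#' pop <- pm_population(x = c(1L, 40L), y = c(1L, 3L),
#'                      threshold = c(0.9, 0.2), x_max = 100, y_max = 25)
#' pop
#' @export
pm_population <- function(x, y, threshold, generation = 0L,
                          x_max = 100L, y_max = 25L,
                          resident = rep(NA, length(x))) {
  pop <- list(generation = as.integer(generation),
              x = as.integer(x), y = as.integer(y),
              threshold = as.numeric(threshold),
              resident = as.logical(resident),
              x_max = as.integer(x_max), y_max = as.integer(y_max))
  class(pop) <- "pm_population"
  validate_population(pop)
  pop
}

validate_population <- function(pop) {
  n <- length(pop$x)
  if (length(pop$y) != n || length(pop$threshold) != n ||
      length(pop$resident) != n)
    stop("population vectors must have equal length", call. = FALSE)
  if (n > 0L) {
    if (any(pop$x < 1L) || any(pop$x > pop$x_max) ||
        any(pop$y < 1L) || any(pop$y > pop$y_max))
      stop("individual coordinates outside the landscape", call. = FALSE)
    if (any(pop$threshold < 0) || any(pop$threshold > 1) ||
        anyNA(pop$threshold))
      stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  if (pop$generation < 0L) stop("negative generation", call. = FALSE)
  invisible(pop)
}

#' Number of individuals in a population
#' @param pop A `pm_population`.
#' @return Integer count.
#' @export
population_size <- function(pop) length(pop$x)

#' Phenotype labels of a population
#'
#' @param pop A `pm_population`.
#' @return A factor with levels `migrant`, `resident`, `undecided`.
#' @export
phenotypes <- function(pop) {
  lab <- ifelse(is.na(pop$resident), "undecided",
                ifelse(pop$resident, "resident", "migrant"))
  factor(lab, levels = c("migrant", "resident", "undecided"))
}

# linear patch index 1 .. x_max*y_max
patch_index <- function(pop) (pop$y - 1L) * pop$x_max + pop$x

#' @export
print.pm_population <- function(x, ...) {
  n <- population_size(x)
  cat(sprintf("pm_population: generation %d, %d individuals on a %d x %d landscape\n",
              x$generation, n, x$x_max, x$y_max))
  if (n > 0L) {
    occ <- length(unique(patch_index(x)))
    cat(sprintf("  occupied patches: %d; threshold range [%.3f, %.3f]\n",
                occ, min(x$threshold), max(x$threshold)))
    ph <- table(phenotypes(x))
    cat(sprintf("  phenotypes: %d migrant, %d resident, %d undecided\n",
                ph[["migrant"]], ph[["resident"]], ph[["undecided"]]))
  }
  invisible(x)
}
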