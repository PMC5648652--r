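---
title: "Modelling partial migration with a genetic threshold trait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling partial migration with a genetic threshold trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partmig)
```

## The model

`partmig` simulates a haploid species with discrete, non-overlapping
generations on a rectangular breeding landscape of `x_max = 100` columns by
`y_max = 25` rows of patches, each with carrying capacity `K = 100`. The
x-axis is a pole-to-equator gradient: nominal resident winter survival rises
linearly as $0.01x$ (0.01 at the polar edge, 1 at the equatorial edge),
while the reproduction location factor falls linearly from 1 to 0.8. Each
individual carries a single continuous heritable trait, the migration
threshold $T \in [0,1]$, expressed as a binary phenotype: the individual
migrates for the winter exactly when its expected local winter survival is
strictly below $T$.

One generation consists of four stages.

**Decision.** The survival expectation includes resident density, which is
itself the outcome of the patch's decisions. We resolve this simultaneity
with a fixed point that realizes perfect anticipation: sort the patch's
thresholds ascending and let the resident count $n^\ast$ be the largest $n$
such that the $n$-th smallest threshold satisfies
$T_{(n)} \le s_r(x, n)$, where

$$s_r(x, N_r) = 0.01x\left(1 - (1 - c\_dens_s)\,\frac{N_r}{K}\right),$$

clamped to $[0,1]$. Because $T_{(n)}$ is non-decreasing and $s_r(x, n)$
non-increasing in $n$, the qualifying set is a prefix of the sorted order
and $n^\ast$ is unique; the $n^\ast$ smallest-threshold individuals stay.
Ties at the marginal threshold value are broken uniformly at random. At the
realized density every resident's $T$ is at most the realized survival, and
every migrant would fall below its threshold even as the $(n^\ast{+}1)$-th
resident, so no individual regrets its decision. Alternative readings —
sequential decisions in random order, or decisions against the previous
generation's density — converge to the same partition only approximately
and introduce an arbitrary ordering or a one-generation lag; we consider
the fixed point the strongest reading of "individuals perfectly predict
their local survival" and did not pursue them further.

**Winter survival.** Migrants survive with the constant $s_m = 0.5$:
migrant mortality is dominated by the journey, and migrants are assumed to
move on if a wintering site is crowded, so no density term applies.
Residents survive with $s_r(x, N_r)$ evaluated at the resident count fixed
at decision time. With the default $c\_dens_s = 0.6$, resident survival
reaches zero at density $N_r/K = 2.5$.

**Dispersal.** Each survivor relocates with probability $d = 0.1$ to a cell
drawn uniformly from the Chebyshev neighborhood of radius $\delta = 2$ (24
candidate cells in the interior), excluding the origin. The landscape has
reflecting ("bouncing") borders: an out-of-range coordinate is mirrored
back (`x' = 2 - x` at the low edge, `x' = 2 x_max - x` at the high edge),
and the draw is repeated in the rare case (possible only on very narrow
landscapes) that reflection lands back on the origin. The kernel is uniform
over cells rather than over distances: the Chebyshev disc is the natural
isotropic neighborhood on a square grid, and nothing in the biology
suggests distance-biased settlement at these scales.

**Reproduction.** Each survivor draws a raw brood size from the discrete
uniform $\{0, \dots, 6\}$ (mean 3) and multiplies it by

$$c_{tot} = \left(1 - 0.01x\,(1 - c\_loc_r)\right)
            \left(1 - (1 - c\_dens_r)\,\frac{N}{K}\right),$$

with $N$ the patch total after dispersal, both phenotypes counted, clamped
to $[0,1]$; migrant parents are additionally multiplied by
`migr_repro_factor` when the degraded-migrant-reproduction change is
active. The resulting non-integer expectation $R$ is realized by
*stochastic rounding*, $\lfloor R \rfloor$ plus a Bernoulli draw on the
fractional part. This is the smallest-variance integerization that
preserves $E[R]$ exactly; plain rounding or truncation would bias the
growth rate by up to half an offspring per parent. Offspring inherit the
mother's threshold and mutate with probability $m = 10^{-4}$ to a fresh
uniform draw on $[0,1]$ (the mutational kernel is a resampling, not a
perturbation, so the trait can jump across the whole range but never leave
it). All parents die.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `K` | 100 | carrying capacity per patch (individuals) |
| `s_m` | 0.5 | migrant winter survival (probability) |
| `c_dens_s` | 0.6 | survival density dependence (1 = none) |
| `c_dens_r` | 0.4 | reproduction density dependence (1 = none) |
| `c_loc_r` | 0.8 | reproduction location dependence (1 = none) |
| `m` | 1e-4 | per-offspring mutation probability |
| `d` | 0.1 | dispersal probability |
| `delta` | 2 | maximum dispersal distance (cells, Chebyshev) |
| `x_max`, `y_max` | 100, 25 | landscape extent (patches) |
| `max_brood` | 6 | brood-size upper bound |
| `surv_delta` | 0 | additive shift of nominal resident survival |
| `migr_repro_factor` | 1 | factor on migrant offspring number |

`surv_delta` is applied to the nominal term $0.01x$ *before* the density
factor and the result is clamped to $[0,1]$; the environmental changes are
stated as "+0.2"/"−0.2", an additive reading corroborated by the fact that
under the −0.2 shift a threshold of $T = 0.5$ codes migratory exactly up to
the crossover column $x = 70$ ($0.01x - 0.2 < 0.5 \iff x < 70$). The
migrant-reproduction change is multiplicative (×0.8): "20% decreased
reproductive success" has no natural additive unit for a count with mean
$3\,c_{tot}$.

The decision rule is strict (`migrate iff s < T`, equality stays). This
makes $T = 0$ a permanent resident and places the zero-density phenotype
switch for $T = 0.5$ exactly at column 50 at baseline
(`decision_crossover(0.5)`), the anchor for the fast colonization of the
mixed zone from a uniform $T = 0.5$ start.

## Scenarios

`scenario()` bundles an initialization region (`complete`: the whole
landscape; `migrants_only`: columns 1–10; `residents_only`: columns
90–100; every patch of the region starts at `K` individuals), an initial
diversity mode (`maximum`: $T \sim U(0,1]$; `zero`: $T = 0.5$;
`zero_fitted`: $T = 0.1$ for a resident start, $T = 0.9$ for a migrant
start), and an abrupt change (`surv_up`, `surv_down`, `migr_repro`, or
`none`). Changes are step functions applied from `change_generation`
(default 300, when demographic equilibrium has been reached) — except for
the whole-landscape zero-diversity start, where the change applies at
generation 0 so that mutation cannot rebuild diversity before the change
hits. `scenario_catalog()` crosses the 8 valid region × diversity pairs
with the 3 changes into the default 24-scenario set; unchanged
(range-expansion) runs are constructed directly with `scenario()` since
their dynamics are the pre-change phase of the catalog runs. Replicate `i`
of a set runs with seed `base_seed + i`, and identical (scenario,
parameters, seed) triples give bit-identical trajectories.

## Summaries

Phenotypes are counted and thresholds averaged per x-column. The
partial-migration zone is bounded by the *polar border* (smallest column
whose residents are at least 1% of that column's decided individuals) and
the *equatorial border* (largest column with at least 1% migrants); width
is their difference and the zone's location their midpoint (reported as a
real number, possibly half-integer). The 1% criterion is read per column —
a landscape-wide total has no column index to attach "smallest x-location
where" to — and the fraction is of decided individuals, since end-of-run
offspring have not yet expressed a phenotype. The *range front* is the
most advanced occupied column (≥ 1 individual by default) relative to the
initialization side. Borders are `NA` while no column qualifies (e.g.
before a range expansion reaches the mixed zone); replicate aggregation
reports mean, sample SD and the contributing replicate count per
generation, excluding missing values.

## Numerical and degenerate cases

Thresholds remain in $[0,1]$ by construction (mutation resamples within
the interval). An empty landscape propagates through all four stages and
summaries as an empty population with `NA` borders and front. Without
mutation the set of distinct threshold values can never grow. All
probabilities and factors are clamped to $[0,1]$ after composition, so
extreme densities give extinction (survival 0) or reproductive failure
($c_{tot} = 0$) rather than negative rates.

## Scale used in the automated checks

The package's stochastic regression checks run the full scenario design at
a reduced scale — a 100 × 5 landscape with `K = 50`, 10 replicates of 400
generations per scenario class — which preserves the x-resolution of the
gradients (the quantity all summaries are indexed by) while cutting the
per-generation population about tenfold. Two consequences are worth
keeping in mind when extrapolating to the full scale. First, the mutation
supply per generation scales with the number of births, so
mutation-limited processes are about ten times slower: in particular the
fitted-threshold range expansions, whose colonization of the mixed zone
requires de novo variation, are expected to remain incomplete within 400
generations at this scale (they are the slowest class in the full-scale
model too — the reduced scale exaggerates, but does not create, that
ordering). Second, with only 5 rows a column holds at most a few hundred
individuals, so the 1% border criterion can be tripped by a handful of
individuals and the zone borders fluctuate more between generations than
they would with 25 rows; window averages over ~20 generations are used
wherever a location is compared.

What passing these checks shows is internal: the implemented decision,
survival, dispersal and reproduction rules jointly reproduce the model's
qualitative equilibrium (the tripartite migrant / mixed / resident
structure), the direction of zone shifts under the three abrupt changes,
and the diversity-ordering of colonization speeds. The generator emulates
the model's own assumptions — discrete generations, haploid asexual
inheritance, deterministic gradients, perfect survival prediction — not
field data; none of this validates the threshold model against real
populations.

## Known limitations

Diploid or sexual genetics, multiple loci, environmental stochasticity in
the gradients, imperfect survival prediction, and gradual (ramped) forcing
are out of scope. The published selection of 24 scenario combinations is
reconstructed from the stated options and constraints; the catalog is
overridable should a different selection be needed.
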