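---
title: "Representation and metapopulation clustering in a zoo network: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representation and metapopulation clustering in a zoo network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoometapop)
```

This vignette is the package's own account of its two analyses, the
assumptions behind them, the parameters that matter, and the design choices
made where more than one reasonable implementation existed.

## 1. The representation test

### Model

A zoo network holds `z` species of a taxonomic order out of `n` described
worldwide, `m` of which are threatened (Red List categories VU, EN or CR).
If collections were assembled without regard to threat status — the null of
*unplanned collection* — the held species would be a uniform draw without
replacement from the world checklist, and the number of threatened species
among them would be hypergeometric. The package provides both routes to this
null distribution:

* `simulate_representation_pmf()` — the resampling route: `S` independent
  draws of `z` species from the pool, tallied into an empirical probability
  mass function. Every probability is a multiple of `1/S` and the mass sums
  to one (checked to 1e-12 in tests).
* `hypergeometric_pmf()` — the analytic route, used both as the default
  analysis engine and as the oracle against which the simulation is tested
  (total variation distance below 0.02 at `S = 20,000`).

### Classification

`classify_order()` reports the point probability of the observed count `w`
(the historical "analogue to the P-value") but classifies by cumulative
tails: `under_represented` iff `P(J <= w) <= alpha`, `over_represented` iff
`P(J >= w) <= alpha`. Tails, not point masses, realize the 0.05/0.95
quantile rule exactly: a point mass at the observed value gives both tails
equal to one and is correctly indistinguishable, whereas a point-probability
rule would be undefined or misleading there. Ties at the quantile are
inclusive (`<=`). The identity `lower + upper - point = 1` holds by
construction and is asserted in the tests.

Because the support is discrete, the achieved size of each one-sided test is
at most `alpha` and usually below it; the test is conservative. No
multiple-testing correction is applied across orders — verdicts are
per-order descriptions, not a family-wise inference — and this is a
deliberate fidelity choice, documented rather than "fixed".

### Parameters

| parameter | default | units | why |
|---|---|---|---|
| `alpha` | 0.05 | – | conventional two-tail bound of the null PMF |
| `iterations` (S) | 10,000 | draws | "several thousand" resampling steps; large enough that 1/S resolution is far below alpha |
| `engine` | `"exact"` | – | the null law is exactly hypergeometric; Monte Carlo is kept for fidelity and testing |

Orders held nowhere (`z = 0`) are reported as `not_held` and left
unclassified: with nothing sampled the test statistic is degenerate, and
flagging such orders as under-represented would conflate absence with
significance.

## 2. Metapopulation clusters

### Model

For a threatened species, a focal zoo and a radius `r` (km), the cluster is
every zoo within great-circle distance `r` (inclusive, so the focal zoo is
always a member and clusters nest as `r` grows). The cluster's
metapopulation size is the pooled holding count, and the event of interest
is reaching a threshold `m` of 50, 100 or 250 individuals: 50 as the
historical short-term minimum viable population, 250 as the Red List's
"very small wild population" bound for Critically Endangered, 100 as an
intermediate. The attainment probability per radius is estimated by:

* `mc_cluster_probability()` — focal zoos drawn uniformly *with replacement*
  from **all** zoos (2,000 iterations by default). Drawing from all zoos,
  not just holders, makes the probability interpretable as network-wide
  coverage: it answers "starting anywhere in the network, how likely is a
  radius-r coordination effort to assemble the threshold?".
* `exhaustive_cluster_probability()` — every zoo once as focal; exact, and
  the default engine at desk scale since a precomputed distance matrix makes
  it cheaper than simulation.

Species whose network-wide total never reaches `m` are excluded
(`eligible_species()`); the threshold comparison is `N >= m` ("at least m"),
with a `strict` switch for `N > m` since published table labels sometimes
read "> m". Mean cluster size and mean number of member zoos holding the
species are averaged over *all* sampled clusters, not only threshold-meeting
ones, matching the unconditional form of the averaging.

Per class, `class_ratio_curve()` averages `p / d_r` over eligible species
and `optimal_cluster()` takes the grid argmax — the radius where attainment
probability is highest per km of coordination distance. Ties take the
smallest radius (the tightest-cluster, most conservative recommendation).
The grid starts at 100 km so the ratio's divisor is never zero; radius 0 can
still be evaluated diagnostically on the probability curves.

### Numerical choices

* Distance is haversine on a 6,371 km sphere — the source analyses never
  state a metric, but all radii are continental-scale km, where the sphere
  approximation errs by well under one grid step.
* Monotonicity of the exhaustive probability in `r` is exact (nested
  clusters) and asserted, with saturation to 1 past the network diameter.
* The Monte Carlo engine is tested against the exhaustive oracle within
  three binomial standard errors plus `1/S`.

## 3. The synthetic-data generator

The generator (`synthetic_scenario()`, `generate_dataset()`) emulates the
*shape* of a global zoo-network inventory, not any real institution:

* zoos scattered with Gaussian spread (km) around continental region
  centres — the default demo puts 20 zoos in two regions ~7,600 km apart,
  giving the bimodal distance structure that makes ratio curves non-trivial;
* per-order world checklists with species totals spanning orders of
  magnitude (defaults 300–5,000) and stated threatened fractions;
* which species are held: a weighted draw without replacement per order,
  weight `beta` for threatened species. `beta = 1` *is* the null hypothesis
  of the representation test — held threatened counts are then exactly
  hypergeometric, which the calibration tests exploit. The optional
  `z_target` pins the number of held species per order so power studies
  (e.g. `beta = 5` or `beta = 0` at n = 200, m = 60, z = 40) run at exactly
  the stated configuration;
* per-species global abundance from a discretized Pareto,
  `round(scale * U^(-1/shape))` capped at `cap` (defaults shape 1.2, scale
  35, cap 20,000): about 72% of species below 100 individuals and about 2%
  above 1,000, the right-skewed banding seen in real inventories;
* abundance split across `1 + Poisson(zoo_intensity * log10(1 + total))`
  zoos, each holding at least one individual, so common species are spread
  over more institutions; an optional `range_clustering` knob concentrates a
  species' holders near an anchor zoo (distance-decay, default off).

What a green test on synthetic data does **not** establish: real networks
have correlated taxonomy and geography (regional collection fashions,
rescue-centre concentrations), institution-size heterogeneity, and temporal
turnover, none of which are modelled. Green tests establish the *algorithms*
(calibration, power, oracle agreement, monotonicity), not any empirical
claim about real zoo holdings — the published network-level results were
computed on proprietary data and are out of scope here.

Scenario files are JSON (see `read_scenario()`); YAML is not supported
because no YAML parser is available in the supported dependency set.

## 4. Reporting conventions

Percentages are rounded half away from zero (the convention of printed
inventory tables; base R rounds half to even). Population-band matrices use
clean half-open intervals `(lower, upper]` with default edges 0, 50, 100,
250, 500, 1,000, 2,000, Inf — species with 1–50 individuals genuinely land
in the 0–50 band, unlike some published tables where that row is printed
empty and absorbed into 50–100; the divergence is intentional and
documented.

## 5. Known limitations

* Counts are treated as a single snapshot; demographic structure, breeding
  suitability, kinship and inbreeding are out of scope — thresholds are pure
  headcounts.
* A species belongs to exactly one (class, order); subspecies and hybrids
  must be pre-aggregated upstream.
* No taxonomic name resolution, no live registry or Red List API access.
* The ratio optimum depends on the grid; with the default 100 km step the
  argmax is resolved to the step size, and ties (rare on continuous data)
  resolve to the smaller radius.
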