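---
title: "Models and methods behind axocycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind axocycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axocycle)
```

axocycle implements the quantitative analyses used to characterize neural
stem cell behaviour in the regenerating axolotl spinal cord: cell-cycle
kinetics from cumulative thymidine-analog labeling, mitotic-index
estimation from sectioned tissue, mitotic-spindle and cleavage-plane
orientation statistics, and an nCounter expression pipeline. This vignette
explains each model, its assumptions, the tunable parameters, and the
numerical and design choices made where several defensible options
existed. Every quantitative statement here is computed by the package's
own functions and checked in its test suite; none is quoted from
elsewhere.

## The cumulative-labeling model

Under continuous availability of a thymidine analog (BrdU or EdU), every
cell that passes through S-phase becomes permanently labeled, and the
labeled fraction of the population rises over time until all cycling cells
have been through S. The shape of that curve encodes the cycle length
`T_C`, the S-phase length `T_S`, the combined G2+M length `T_G2M`, the
initial growth fraction `GF` (the fraction of counted cells that are
cycling at labeling onset), and the division mode `r` — the average number
of daughters per division that remain proliferative. Neurogenic
(asymmetric) divisions have `r = 1`; symmetric proliferative divisions
have `r = 2`. Intermediate values are accepted by the model functions
since `r` is an average, but fitting fixes it at one of the two biological
modes.

The model factors as `R(t) = g(t) R'(t)`. `R'(t)` is the labeled fraction
among cycling cells of an asynchronous population with constant phase
lengths (see `?rprime` for the piecewise form). Three structural
properties pin the formula down: it is continuous at both breakpoints
(`t = T_G2M` and `t = T_C - T_S`), it reduces to the linear
`(T_S + t)/T_C` form as `r -> 1`, and `R'(0)` equals the steady-state
S-phase occupancy of the age distribution. All three are enforced as
property tests over randomly drawn parameter sets, and the whole curve is
checked against an independent agent-based simulation (below).

The growth-fraction correction `g(t)` differs by division mode. Under
`r = 2`, cycling cells double every `T_C` while postmitotic cells stay
constant, so `g(t) = GF·2^(t/T_C) / (GF·2^(t/T_C) + 1 - GF)` rises toward
one. Under `r = 1`, every division replaces its mother with exactly one
cycling daughter, and the postmitotic sibling is excluded from counting
(in the source measurements, rounded neuronal nuclei are excluded), so the
counted denominator is constant and `g(t) = GF` for all `t`. The `r = 1`
curve therefore saturates at `GF`, which is why the empirical plateau of a
cumulative-labeling curve estimates the growth fraction for neurogenic
populations.

Time is measured from the first label injection and the repeated-injection
schedule is idealized as continuous label availability. The
injection-interval discretization is deliberately not modelled; for
injection intervals well below `T_S` the idealization is exact for every
cell that enters S between injections.

## Fitting and confidence intervals

`fit_cell_cycle()` minimizes the weighted sum of squared errors
`SSE = sum_i n_i ((Rexp_i - R(t_i))/sigma_i)^2`, where a timecourse row
holds the across-animal mean fraction, the across-animal standard
deviation `sigma_i`, and the number of animals `n_i`. The `n_i` factor
makes the aggregated table exactly equivalent to summing over individual
measurements weighted by their timepoint's standard deviation (replacing
each animal's value by the timepoint mean shifts the SSE only by a
parameter-independent constant, so the minimizer and the curvature are
unchanged). Zero or missing standard deviations are rejected; an
explicit `unweighted = TRUE` flag substitutes unit weights.

`r` is never fitted — it is set by the population's division mode.
`T_G2M` is fixed at 9 h by default: the labeled-mitoses curve saturates
once the cells that were in S at labeling onset have traversed G2 and
entered M, so `estimate_tg2m()` reads `T_G2M` off as the earliest
sustained saturation time of that curve, and 9 h is the value obtained for
these populations. Any parameter can be fixed through `fixed =`.

The SSE surface of the piecewise model has local minima, so optimization
starts from the best five points of a coarse grid (`T_C` 50–500 h in steps
of 50, `T_S` at 10–50% of `T_C`, `GF` 0.5–1.0 in steps of 0.1 — all
overridable) and refines each with the bounded quasi-Newton `nlminb`.
Infeasible regions (`T_S + T_G2M >= T_C`, `GF` outside (0,1]) are handled
by a large finite penalty.

68% confidence half-widths use the parabolic approximation: since the
weighted SSE is a chi-square-type objective, the 1-sigma contour is
`SSE_min + 1`, giving covariance `2 H^{-1}` with `H` the numerically
differentiated Hessian at the optimum. For curvature evaluation the
`GF <= 1` wall is lifted (the model formulas extend smoothly past 1), so
finite differencing near `GF = 1` stays clean. A fit is reported as
converged when the optimum is finite and `H` is positive definite — the
condition under which the intervals exist; the raw `nlminb` code is kept
for diagnostics because it reports "false convergence" when started at an
exact optimum. Calibration is checked empirically: over 200 simulated
experiments at the regeneration design (12 h sampling to 120 h, 5 animals
of 200 counted cells per timepoint, truth `T_C` = 119 h, `T_S` = 88 h,
`T_G2M` = 9 h, `GF` = 0.96, `r` = 2), the median relative error of the
recovered `T_C` must stay below 10% and the 68% interval must cover the
truth at a rate consistent with its nominal level (55–80% acceptance
band); both run in the test suite.

Derived quantities follow by algebra and linear error propagation:
`T_M = mi · T_C` with the mitotic index `mi`, and
`T_G1 = T_C - T_G2M - T_S`, with fixed parameters contributing zero
error. `extrapolate_full_cycle_differentiation()` linearly rescales an
observed differentiated fraction by the fraction of cells that completed
a full cycle during the chase (an input, not recomputed), capping at 1.

## The agent-based oracle

`simulate_labeling_experiment()` is an independent implementation of the
same biology used to validate the closed form. Founder ages are drawn
from the steady-state age density (uniform for `r = 1`, proportional to
`2^(-a/T_C)` for `r = 2`); a binomial share `GF` of founders is cycling.
Because phase lengths are constant, all descendants of a founder share
its cycle position and label state, so lineages are propagated
deterministically: a founder of age `a0` has divided
`floor((a0 + t)/T_C)` times by `t` and contributes `r^k` counted cells.
The labeled fraction is a weighted average over founders; its Monte-Carlo
standard error is binomial in the number of *founder lineages* (not in
the counted-cell total — descendants are perfectly correlated), and the
oracle-agreement tests use three such standard errors at 100,000 lineages
over 20 random parameter sets per division mode.
`simulate_labeling_timecourse()` wraps the simulator into replicated
animal-level measurements; the across-animal standard deviation is
floored at 0.001 so plateau timepoints where all animals coincide keep a
finite fitting weight.

## Mitotic index

Proliferating cells are counted in one optical plane per section while
mitotic figures are counted through the full physical section, so the
optical count is scaled by `l_s / l_c` (section thickness over mean AP
nucleus length; `l_c` is measured per replicate, and because it is
approximately equal across these cell populations a pooled value may be
substituted when a replicate lacks its own). The per-section index is
`mi = N_M / N_P`; sections with no proliferating cells are excluded (they
cannot form an index) and the exclusion is reported. Sampling a finite
number `n_s` of the `ns_total = (l_max - l_min)/l_s` sections spanning
the region makes the replicate error a finite-population-corrected
s.e.m., `sqrt((ns_total - n_s)/(ns_total - 1)) · sd/sqrt(n_s)`; a census
has zero sampling error. `ns_total` is rounded to the nearest integer
with a warning when the region is not an integer number of sections.

Across biological replicates the population error *adds* the mean
intra-replicate error and the inter-replicate s.e.m. This additive
combination is unconventional (quadrature would be standard) but is kept
as the package's primary definition to match how these measurements'
errors were originally combined; `combine = "quadrature"` is available
for sensitivity analysis, and is always the smaller of the two, so the
additive default is conservative. Calibration on synthetic sections
(Poisson optical counts, binomial mitoses at a known true index) requires
the population estimate to fall within three reported errors of the truth
in at least 95% of 200 seeded runs.

## Division-orientation statistics

Each measured anaphase/telophase cell carries its own AP axis (two points
in the middle of the central canal at either end of its image stack), so
no global axis is assumed. The projection statistic is the absolute
scalar product of the unit spindle vector and the unit AP vector.
Although a dot product of unit vectors lies in [-1, 1], the stated range
of the statistic is [0, 1]: the absolute value is the only reading
consistent with that range, and it has the attractive property that for
uniformly random 3D orientations `|cos θ|` is *exactly* Uniform(0, 1) —
which is precisely the null the test assumes. The test declares a region
oriented when the mean projection of its `N` cells exceeds
`0.5 + 1.96/sqrt(12N)` (uniform mean 0.5, s.d. `1/sqrt(12)`, one-sided
normal approximation at level 0.025). No small-sample correction is
applied — a documented limitation, acceptable at the `N >= 10` regimes
this test is used in; its empirical type-I error at `N = 30` is checked
against the nominal level over 10,000 null simulations.

Zone assignment (e.g. to the Prickle1-expressing caudal zone) uses a
closed interval on AP position with bounds supplied by the user — the
package does not infer zone bounds.

Cleavage-plane analysis is two-dimensional: in a longitudinal optical
section the cleavage direction is the spindle direction rotated 90°, and
the reported angle is the acute angle between that direction and the
apical surface, in [0°, 90°] — 90° ("vertical" cleavage, the symmetric
division geometry) when the spindle parallels the apical surface. Group
comparisons use the Mann–Whitney U test: exact when the pooled sample is
tie-free and at most 20, otherwise the midrank normal approximation with
tie-corrected variance and no continuity correction.

## nCounter expression pipeline

Normalization runs in four steps, in order: (1) per-sample scaling so the
geometric mean of the spike-in positive probes matches the across-sample
mean of those geometric means; (2) a detection call per gene — one-tailed
pooled-variance t-test of the gene's counts across the compared samples
against the pooled negative-control counts of the same samples, with
`p >= 0.05` called absent and blanketed to 1; (3) subtraction of the
negative-control mean plus three standard deviations, floored at 1
(computed per sample by default, since background is sample-specific
chemistry; a pooled alternative is a flag); (4) per-sample scaling to
equalize the housekeeping probe (*Rpl4* in the motivating CodeSet).
Because detection granularity is not uniquely determined by the original
description, the package tests each gene within the samples of each
comparison — matching the role of the call as a precondition for that
comparison's differential test. Note two structural facts checked in the
tests: the chain restores between-sample ratios after a technical
rescaling of any lane (up to the global mean target), and its only true
fixed point is a background-free matrix — a subtractive background step
is never idempotent when negatives are positive.

Differential expression uses a two-group exact conditional
negative-binomial test written for this package: with group sums `K_a`
and `K_b` and a per-gene dispersion `alpha`, the group sums are NB with
means `n_a·mu` and `n_b·mu` and sizes `n_a/alpha`, `n_b/alpha`, and the
p-value is the total probability of splits of `K_a + K_b` no more likely
than the observed one. Dispersion is estimated per gene by the method of
moments on within-group variances and shrunk toward a parametric trend
`alpha(mu) = a0 + a1/mu` fitted across genes; the larger of the gene and
trend values is used (floored at 1e-8), a conservative sharing rule
chosen because moment estimates at `n = 3` per group are noisy and the
priority is type-I control — verified on all-null synthetic matrices,
alongside a ≥90% sensitivity requirement at 4-fold changes with
dispersion 0.05. Normalized counts are rounded for the conditional
computation. Fold changes are computed on group means floored at 1, so a
gene blanketed everywhere has `log2FC = 0`; significance is raw
`p < 0.05`, with BH-adjusted values reported alongside. Matching any
specific external DE package's numbers is a non-goal; validation is
against generator truth.

The concordance analysis takes a 100-gene developmental reference (50
genes low and 50 high in stem-zone-like tissue) and counts a
development-low gene as concordant if significantly down at either
regeneration timepoint, a development-high gene if significantly up at
either; the class-by-concordance 2×2 table is tested with Fisher's exact
test (two-sided, point-probability convention). Raw `p < 0.05` is the
default significance notion for these calls, configurable upstream via
the DE threshold.

## Synthetic-data generators and their scope

The generators provide every input format the analyses read, with
recorded ground truth and full determinism given a seed. Their defaults
describe the motivating study's conditions: regeneration-like labeling
designs (12 h grids to 120 h, 5 animals per timepoint, ~200 counted
cells per animal), 50 μm sections over a 500 μm region with ~12.5 μm
nuclei, six positive probes in a geometric titration, eight
Poisson-background negatives, one housekeeping probe, three samples per
group, and log-normal technical lane factors (s.d. 0.2 on the log scale).
Orientation sampling uses a Watson-type axial family
(`density ∝ exp(κ cos²θ)`, sampled by numeric inverse-CDF on `|cos θ|`)
that reduces exactly to the uniform sphere at `κ = 0`;
`solve_concentration()` inverts the mean projection for power studies.

What the generators deliberately do not emulate: spatial structure within
sections, cell-cycle length variability between cells (phase lengths are
constant by model assumption (i)), label dilution or washout,
probe-specific hybridization efficiencies, and batch structure beyond a
single scale factor per lane. Passing the synthetic-data validations
therefore shows the estimators are correct *under the stated model
assumptions*, not that real tissue satisfies those assumptions.

## Problem sizes used in validation

The test suite exercises: 100,000 founder lineages per oracle comparison
(20 random parameter sets per division mode, 10-point grids); 1,000
random parameter sets for breakpoint continuity and 50 for the `r -> 1`
limit; 200 simulated labeling experiments for recovery/coverage; 200
seeded section datasets; 100 all-null and 20 spiked expression matrices
of 100 genes; 10,000 null samples for test calibration; exhaustive
enumeration of all 2×2 tables with total at most 40 and all rank
configurations with group sizes at most 6. These sizes were chosen so
each Monte-Carlo acceptance band is a few standard errors wide.

## Known limitations

- The parabolic (symmetric) confidence intervals can misrepresent
  strongly asymmetric SSE valleys, e.g. when the sampling window barely
  reaches the plateau; profile likelihood would be the next step up.
- The orientation test's normal approximation is anticonservative for
  very small `N`; an exact test of the uniform mean would need the
  Irwin–Hall distribution.
- The additive error combination for the population mitotic index is not
  a variance decomposition; it is kept for fidelity with the original
  measurements and bounded below by the quadrature option.
- The NB test conditions on rounded normalized totals; for counts near 1
  (heavily blanketed genes) the discreteness makes calls conservative.
- `estimate_tg2m()` reads saturation off the observed grid, so its
  resolution is the sampling interval of the labeled-mitoses curve.
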