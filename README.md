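# axocycle

Quantitative analysis toolkit for studies of neural stem cell behaviour in
the regenerating axolotl spinal cord — and, more generally, for any system
measured with cumulative thymidine-analog labeling, sectioned-tissue
mitotic counts, 3D mitotic-spindle coordinates, or NanoString
nCounter-style count matrices.

After tail amputation, the SOX2⁺ neural stem cells lining the central
canal switch from slow, neurogenic (asymmetric) divisions to fast,
proliferative (symmetric) divisions, orient their mitotic spindles along
the anterior-posterior (AP) axis, and reactivate an embryonic-like gene
expression program. Quantifying that switch requires four statistical
machines, all implemented here:

1. **Cell-cycle kinetics from cumulative labeling.** Under continuous
   BrdU/EdU availability the labeled fraction follows
   `R(t) = g(t)·R′(t)`, where `R′(t)` is the piecewise labeling curve of
   an asynchronous population with constant phase lengths `T_C`, `T_S`,
   `T_G2M`, and the growth-fraction correction is
   `g(t) = GF·r^(t/T_C) / (GF·r^(t/T_C) + 1 − GF)` for proliferative
   divisions (`r = 2`) or the constant `GF` for neurogenic divisions
   (`r = 1`). Parameters are estimated by weighted least squares
   (`SSE = Σ n_i((Rexp_i − R(t_i))/σ_i)²`) with 68% confidence intervals
   from the parabolic approximation (ΔSSE = 1), and phase lengths are
   derived as `T_M = mi·T_C`, `T_G1 = T_C − T_G2M − T_S` with linear
   error propagation.
2. **Mitotic index with finite-population errors.** Per-section indices
   `mi = N_M/(N_PCNA·l_s/l_c)` are averaged per replicate with a
   finite-population-corrected s.e.m.
   `√((ns_total − n_s)/(ns_total − 1))·σ/√n_s`, then across replicates
   with the additive intra + inter error combination.
3. **Division-orientation statistics.** The projection of the unit
   spindle vector on the per-cell AP axis, `|S·AP| ∈ [0,1]`, is exactly
   Uniform(0,1) for random 3D orientations; a region is "oriented" when
   its mean projection exceeds `0.5 + 1.96/√(12N)`. Cleavage-plane angles
   (2D) and Mann-Whitney group comparisons are included.
4. **nCounter expression pipeline.** Positive-control geometric-mean
   normalization → detection t-test against negative controls →
   background (mean + 3 s.d.) subtraction with blanketing to 1 →
   housekeeping normalization, followed by an exact conditional
   negative-binomial test per gene with BH adjustment, and a concordance
   analysis against a developmental reference gene set with Fisher's
   exact test.

Every analysis has a matching synthetic-data generator with recorded
ground truth (an agent-based cell-population simulator, a Watson-type
axial orientation sampler, NB count matrices with spike-in controls,
per-section count tables), which the test suite uses as independent
oracles. See the methods vignette (`vignettes/axocycle-methods.Rmd`) for
models, assumptions and design choices.

## Worked example

Simulate a regeneration-like labeling experiment (5 animals × 200 cells
per timepoint, 12 h sampling) and recover the cell-cycle parameters:

```r
library(axocycle)

truth <- cell_cycle_params(T_C = 119, T_S = 88, T_G2M = 9, GF = 0.96, r = 2)
sim <- simulate_labeling_timecourse(truth, seed = 42)
fit <- fit_cell_cycle(sim$timecourse, r = 2, fixed = list(T_G2M = 9))
fit
#> Cumulative-labeling model fit
#> Cell-cycle parameters (r = 2, proliferative divisions)
#>   T_C = 116.53 h  T_S = 86.18 h  T_G2M = 9.00 h  GF = 0.959
#>   T_C   =  116.531  +/- 9.351 (68% CI)
#>   T_S   =   86.181  +/- 8.525 (68% CI)
#>   GF    =    0.959  +/- 0.003 (68% CI)
#>   T_G2M =    9.000  (fixed)
#>   SSE = 0.3651 over 11 points; converged: TRUE
```

The true `T_C` of 119 h is recovered as 116.5 ± 9.4 h: the cycle length,
S-phase length and growth fraction are all within one 68% interval of the
generating values. Combining the fit with a mitotic index gives the phase
lengths:

```r
mi <- population_mitotic_index(list(list(mi = 0.04, dmi = 0.01),
                                    list(mi = 0.06, dmi = 0.01)))
mi
#> Mitotic index: 0.0500 +/- 0.0200 (n = 2 replicates)
derive_phase_lengths(fit, mi = mi$mi, dmi = mi$dmi)[c("T_M", "dT_M")]
#> $T_M
#> [1] 5.826547
#> $dT_M
#> [1] 2.380993
```

i.e. an M-phase of ~5.8 ± 2.4 h. Orientation analysis on 27 synthetic
divisions concentrated toward the AP axis (mean projection 0.7):

```r
kappa <- solve_concentration(0.7)
cells <- sample_spindle_orientations(27, kappa, seed = 7)
orientation_test(spindle_projections(cells)$projection)
#> Orientation test: N = 27, mean projection = 0.6482, threshold = 0.6089
#>   divisions ARE oriented along the AP axis (one-sided, p < 0.025)
```

The mean projection 0.648 exceeds the uniform-null threshold
`0.5 + 1.96/√(12·27) = 0.609`, so these divisions are declared oriented.

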