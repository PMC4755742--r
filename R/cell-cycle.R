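#' Cell-cycle parameter set
#'
#' Bundle of kinetic parameters for an asynchronously cycling population:
#' total cycle length `T_C`, S-phase length `T_S`, combined G2+M length
#' `T_G2M` (all hours) the initial growth fraction `GF` (fraction of counted
#' cells that are cycling at labeling onset), and the division mode `r` —
#' the average number of daughters per division that remain proliferative.
#' `r = 1` describes asymmetric neurogenic divisions (one cycling daughter,
#' one postmitotic daughter), `r = 2` symmetric proliferative divisions.
#'
#' @param T_C Cell-cycle length in hours (> 0).
#' @param T_S S-phase length in hours (> 0).
#' @param T_G2M Combined G2- and M-phase length in hours (>= 0).
#' @param GF Initial growth fraction in (0, 1].
#' @param r Division mode: average proliferative daughters per division,
#'   in \[1, 2\]. The two biological modes are the endpoints (1 neurogenic,
#'   2 proliferative); intermediate averages describe mixed populations and
#'   are accepted by the model, though fitting fixes r at 1 or 2.
#' @return An object of class `cell_cycle_params`.
#' @export
cell_cycle_params <- function(T_C, T_S, T_G2M = 9, GF = 1, r = 1) {
  stopifnot(is.numeric(T_C), is.numeric(T_S), is.numeric(T_G2M),
            is.numeric(GF), is.numeric(r))
  if (r < 1 || r > 2) stop("'r' must lie in [1, 2]")
  if (T_C <= 0 || T_S <= 0 || T_G2M < 0) stop("phase lengths must be positive")
  if (T_S + T_G2M >= T_C) stop("T_S + T_G2M must be smaller than T_C")
  if (GF <= 0 || GF > 1) stop("'GF' must lie in (0, 1]")
  structure(list(T_C = T_C, T_S = T_S, T_G2M = T_G2M, GF = GF, r = r),
            class = "cell_cycle_params")
}

#' @export
print.cell_cycle_params <- function(x, ...) {
  cat(sprintf("Cell-cycle parameters (r = %g, %s divisions)\n", x$r,
              if (x$r == 1) "neurogenic"
              else if (x$r == 2) "proliferative" else "mixed"))
  cat(sprintf("  T_C = %.2f h  T_S = %.2f h  T_G2M = %.2f h  GF = %.3f\n",
              x$T_C, x$T_S, x$T_G2M, x$GF))
  invisible(x)
}

#' Labeled fraction among cycling cells under continuous labeling
#'
#' Closed-form fraction R'(t) of cycling cells carrying label after t hours
#' of continuous thymidine-analog availability, for a population with
#' constant phase lengths and completely asynchronous divisions. For
#' r != 1 the piecewise form is
#' \deqn{R'(t) = \frac{r^{(T_{G2M}+T_S)/T_C} - r^{(T_{G2M}-t)/T_C}}{r-1},
#'   \quad 0 \le t < T_{G2M},}
#' \deqn{R'(t) = 1 - \frac{r^{(T_C+T_{G2M}-t)/T_C} - r^{(T_{G2M}+T_S)/T_C}}
#'   {r-1}, \quad T_{G2M} \le t < T_C - T_S,}
#' and 1 for t >= T_C - T_S. For r = 1 it reduces to (T_S + t)/T_C before
#' saturation. The form is continuous at both breakpoints, reduces to the
#' r = 1 line in the r -> 1 limit, and has R'(0) equal to the steady-state
#' S-phase fraction of an asynchronous population.
#'
#' @param t Time since labeling onset, hours (vectorized, >= 0).
#' @param params A [cell_cycle_params] object.
#' @return Labeled fraction(s) in \[0, 1\].
#' @export
rprime <- function(t, params) {
  stopifnot(inherits(params, "cell_cycle_params"))
  if (any(t < 0)) stop("'t' must be non-negative")
  T_C <- params$T_C; T_S <- params$T_S; G <- params$T_G2M; r <- params$r
  out <- numeric(length(t))
  sat <- t >= T_C - T_S
  out[sat] <- 1
  if (r == 1) {
    out[!sat] <- (T_S + t[!sat]) / T_C
  } else {
    early <- !sat & t < G
    mid <- !sat & t >= G
    out[early] <- (r^((G + T_S) / T_C) - r^((G - t[early]) / T_C)) / (r - 1)
    out[mid] <- 1 - (r^((T_C + G - t[mid]) / T_C) - r^((G + T_S) / T_C)) / (r - 1)
  }
  out
}

#' Growth fraction over time
#'
#' Fraction of the counted population that is cycling at time t. Under
#' proliferative divisions (r = 2) cycling cells double while postmitotic
#' cells remain constant, so the growth fraction rises from its initial
#' value GF: g(t) = GF r^(t/T_C) / (GF r^(t/T_C) + 1 - GF). Under
#' neurogenic divisions (r = 1) each division replaces the mother with one
#' cycling daughter (the postmitotic sibling is excluded from the count),
#' so g(t) = GF for all t.
#'
#' @param t Hours since labeling onset (vectorized).
#' @param params A [cell_cycle_params] object.
#' @return Growth fraction(s) in (0, 1].
#' @export
growth_fraction <- function(t, params) {
  stopifnot(inherits(params, "cell_cycle_params"))
  if (params$r == 1) return(rep(params$GF, length(t)))
  GF <- params$GF
  grown <- GF * params$r^(t / params$T_C)
  grown / (grown + 1 - GF)
}

#' Observed labeled fraction R(t) = g(t) R'(t)
#'
#' The measurable cumulative-labeling curve: the cycling-cell labeled
#' fraction corrected by the growth fraction. For r = 1 the curve saturates
#' at GF; for r = 2 it approaches 1 as the cycling pool outgrows the
#' postmitotic pool.
#'
#' @inheritParams rprime
#' @return Labeled fraction(s) in \[0, 1\].
#' @export
labeled_fraction <- function(t, params) {
  growth_fraction(t, params) * rprime(t, params)
}

#' Weighted sum of squared errors for a labeling timecourse
#'
#' \eqn{SSE = \sum_i ((Rexp_i - R(t_i))/\sigma_i)^2} over the individual
#' measurements of a cumulative-labeling timecourse. The table holds one
#' row per timepoint with the across-animal mean fraction and s.d.; when an
#' `n_animals` column is present each timepoint's squared residual is
#' multiplied by it, which reproduces the per-measurement SSE up to a
#' data-only constant (replacing each animal's value by the timepoint mean
#' changes the SSE by a term independent of the parameters, so the
#' minimizer and the curvature — hence the confidence intervals — are
#' unchanged). Without the column each row counts once.
#'
#' @param timecourse Data frame with columns `time_h`, `fraction_labeled`,
#'   `sd` (per-timepoint standard deviation of the measurements, > 0), and
#'   optionally `n_animals`.
#' @param params A [cell_cycle_params] object.
#' @param unweighted If `TRUE`, missing or zero `sd` values are replaced by
#'   1 (explicit opt-in); otherwise they are an error.
#' @return Non-negative number.
#' @export
labeling_sse <- function(timecourse, params, unweighted = FALSE) {
  tc <- validate_timecourse(timecourse)
  s <- tc$sd
  if (unweighted) {
    s[is.na(s) | s <= 0] <- 1
  } else if (anyNA(s) || any(s <= 0)) {
    stop("all 'sd' values must be positive for weighted fitting ",
         "(set unweighted = TRUE to fit with unit weights)")
  }
  n <- if ("n_animals" %in% names(timecourse))
    as.numeric(timecourse$n_animals) else rep(1, nrow(tc))
  if (any(n < 1)) stop("'n_animals' must be >= 1")
  sum(n * ((tc$fraction_labeled - labeled_fraction(tc$time_h, params)) / s)^2)
}

validate_timecourse <- function(timecourse) {
  need <- c("time_h", "fraction_labeled", "sd")
  miss <- setdiff(need, names(timecourse))
  if (length(miss)) stop("timecourse is missing column(s): ",
                         paste(miss, collapse = ", "))
  keep <- c(need, intersect("n_animals", names(timecourse)))
  tc <- as.data.frame(timecourse)[keep]
  if (any(tc$time_h < 0)) stop("times must be non-negative")
  if (is.unsorted(tc$time_h, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(tc$fraction_labeled < 0 | tc$fraction_labeled > 1))
    stop("labeled fractions must lie in [0, 1]")
  tc
}

# SSE over the free-parameter vector, with a feasibility penalty so the
# optimizer cannot cross T_S + T_G2M >= T_C or leave (0,1] for GF. With
# soft = TRUE the GF <= 1 wall is lifted (the model formulas extend
# smoothly past 1), so finite-difference curvature near GF = 1 is clean.
sse_objective <- function(theta, free, fixed, r, tc, unweighted,
                          soft = FALSE) {
  p <- c(as.list(theta), fixed)
  names(p)[seq_along(theta)] <- free
  if (p$T_C <= 0 || p$T_S <= 0 || p$T_G2M < 0 || p$GF <= 1e-8 ||
      (!soft && (p$GF > 1)) || p$T_S + p$T_G2M >= p$T_C)
    return(1e12)
  pars <- structure(list(T_C = p$T_C, T_S = p$T_S, T_G2M = p$T_G2M,
                         GF = p$GF, r = r), class = "cell_cycle_params")
  labeling_sse(tc, pars, unweighted = unweighted)
}

#' Fit the cumulative-labeling model by weighted least squares
#'
#' Estimates cell-cycle parameters from a cumulative-labeling timecourse by
#' minimizing [labeling_sse]. The division mode `r` is fixed by the biology
#' of the population (1 for neurogenic, 2 for proliferative) and is never a
#' free parameter. `T_G2M` is fixed at 9 h by default (the labeled-mitoses
#' saturation time); any parameter can be fixed via `fixed`. The optimizer
#' is `nlminb` started from the best points of a coarse grid over
#' (T_C, T_S, GF) to avoid local minima of the piecewise surface.
#'
#' 68% confidence half-widths come from the parabolic approximation of the
#' SSE surface: the contour SSE = SSE_min + 1 of the quadratic model, i.e.
#' `sqrt(diag(2 H^-1))` with H the Hessian of the SSE at the optimum.
#'
#' @param timecourse Data frame with columns `time_h`, `fraction_labeled`,
#'   `sd` (see [labeling_sse]).
#' @param r Division mode, 1 or 2.
#' @param fixed Named list of parameters to hold fixed (default
#'   `list(T_G2M = 9)`); names among `T_C`, `T_S`, `T_G2M`, `GF`.
#' @param init Optional named list of starting values for free parameters
#'   (replaces the grid search).
#' @param grid Named list of grid values for the coarse start search;
#'   defaults: `T_C` = 50..500 by 50, `T_S_frac` = 0.1..0.5 of T_C,
#'   `GF` = 0.5..1 by 0.1.
#' @param unweighted Passed to [labeling_sse].
#' @return An object of class `cell_cycle_fit`: list with `params`
#'   (a [cell_cycle_params]), `ci68` (named half-widths for free
#'   parameters), `sse`, `converged`, `fixed`, `free`, `n_points`.
#' @export
fit_cell_cycle <- function(timecourse, r, fixed = list(T_G2M = 9),
                           init = NULL, grid = NULL, unweighted = FALSE) {
  tc <- validate_timecourse(timecourse)
  if (!(r %in% c(1, 2))) stop("'r' must be 1 or 2")
  all_par <- c("T_C", "T_S", "T_G2M", "GF")
  if (length(fixed) && !all(names(fixed) %in% all_par))
    stop("unknown fixed parameter name(s)")
  free <- setdiff(all_par, names(fixed))
  if (length(free) == 0L) stop("at least one parameter must be free")
  if (nrow(tc) < length(free))
    stop("need at least as many timepoints as free parameters")

  gdef <- list(T_C = seq(50, 500, by = 50),
               T_S_frac = seq(0.1, 0.5, by = 0.1),
               GF = seq(0.5, 1.0, by = 0.1))
  if (!is.null(grid)) gdef[names(grid)] <- grid

  starts <- if (!is.null(init)) {
    if (!setequal(names(init), free))
      stop("'init' must name exactly the free parameters")
    matrix(unlist(init[free]), nrow = 1,
           dimnames = list(NULL, free))
  } else {
    cand <- expand.grid(T_C = gdef$T_C, T_S_frac = gdef$T_S_frac,
                        GF = gdef$GF)
    cand$T_S <- cand$T_S_frac * cand$T_C
    cand$T_G2M <- if ("T_G2M" %in% names(fixed)) fixed$T_G2M else 0.05 * cand$T_C
    sses <- vapply(seq_len(nrow(cand)), function(i) {
      th <- unlist(cand[i, free])
      sse_objective(th, free, fixed, r, tc, unweighted)
    }, numeric(1))
    top <- order(sses)[seq_len(min(5L, nrow(cand)))]
    as.matrix(cand[top, free, drop = FALSE])
  }

  lower <- c(T_C = 1e-2, T_S = 1e-2, T_G2M = 0, GF = 1e-3)[free]
  upper <- c(T_C = 5e3, T_S = 5e3, T_G2M = 5e3, GF = 1)[free]

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    ans <- tryCatch(
      stats::nlminb(starts[i, ], sse_objective, lower = lower, upper = upper,
                    free = free, fixed = fixed, r = r, tc = tc,
                    unweighted = unweighted),
      error = function(e) NULL)
    if (!is.null(ans) && (is.null(best) || ans$objective < best$objective))
      best <- ans
  }
  if (is.null(best)) stop("optimization failed from all starting points")

  est <- as.list(best$par)
  names(est) <- free
  full <- c(est, fixed)[all_par]
  params <- cell_cycle_params(T_C = full$T_C, T_S = full$T_S,
                              T_G2M = full$T_G2M, GF = full$GF, r = r)

  # Parabolic 68% CI: SSE behaves as a chi-square objective, so the 1-sigma
  # contour is SSE_min + 1 and cov = 2 H^-1 with H = hessian of the SSE.
  ci <- rep(NA_real_, length(free)); names(ci) <- free
  hess_ok <- FALSE
  H <- tryCatch(
    pracma::hessian(function(th) sse_objective(th, free, fixed, r, tc,
                                               unweighted, soft = TRUE),
                    best$par),
    error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    cov <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cov)) {
      d <- diag(cov)
      if (all(d > 0)) { ci[] <- sqrt(d); hess_ok <- TRUE }
    }
  }

  # a fit counts as converged when the optimum is finite and the SSE
  # surface has positive-definite curvature there (so the parabolic CIs
  # exist); the raw optimizer code is kept for diagnostics because nlminb
  # flags "false convergence" when started at an exact optimum
  structure(list(params = params, ci68 = ci, sse = best$objective,
                 converged = hess_ok && is.finite(best$objective) &&
                   best$objective < 1e11,
                 optim_convergence = best$convergence,
                 fixed = fixed, free = free, n_points = nrow(tc)),
            class = "cell_cycle_fit")
}

#' @export
print.cell_cycle_fit <- function(x, ...) {
  cat("Cumulative-labeling model fit\n")
  print(x$params)
  for (p in x$free)
    cat(sprintf("  %-5s = %8.3f  +/- %.3f (68%% CI)\n", p,
                x$params[[p]], x$ci68[[p]]))
  for (p in names(x$fixed))
    cat(sprintf("  %-5s = %8.3f  (fixed)\n", p, x$fixed[[p]]))
  cat(sprintf("  SSE = %.4g over %d points; converged: %s\n",
              x$sse, x$n_points, x$converged))
  invisible(x)
}

#' Derive M- and G1-phase lengths from a fit and a mitotic index
#'
#' Assuming cells homogeneously distributed in the cycle, the M-phase length
#' is T_M = mi * T_C and G1 follows by subtraction,
#' T_G1 = T_C - T_G2M - T_S. Errors are propagated linearly:
#' \eqn{\Delta T_M = \sqrt{(mi\,\Delta T_C)^2 + (T_C\,\Delta mi)^2}},
#' \eqn{\Delta T_{G1} = \sqrt{\Delta T_C^2 + \Delta T_{G2M}^2 +
#' \Delta T_S^2}} with fixed parameters contributing zero error.
#'
#' @param fit A `cell_cycle_fit` object.
#' @param mi Mitotic index in \[0, 1\].
#' @param dmi 1-sigma error of the mitotic index (default 0).
#' @return List with `T_M`, `dT_M`, `T_G1`, `dT_G1`, `mi`, `dmi`.
#' @export
derive_phase_lengths <- function(fit, mi, dmi = 0) {
  stopifnot(inherits(fit, "cell_cycle_fit"))
  if (!fit$converged) stop("fit did not converge; phase lengths not derived")
  if (mi < 0 || mi > 1) stop("'mi' must lie in [0, 1]")
  err <- function(p) if (p %in% fit$free) fit$ci68[[p]] else 0
  p <- fit$params
  T_M <- mi * p$T_C
  dT_M <- sqrt((mi * err("T_C"))^2 + (p$T_C * dmi)^2)
  T_G1 <- p$T_C - p$T_G2M - p$T_S
  dT_G1 <- sqrt(err("T_C")^2 + err("T_G2M")^2 + err("T_S")^2)
  list(T_M = T_M, dT_M = dT_M, T_G1 = T_G1, dT_G1 = dT_G1,
       mi = mi, dmi = dmi)
}

#' Estimate T_G2+M from a labeled-mitoses timecourse
#'
#' The combined G2+M length is read off the percent-labeled-mitoses curve as
#' the earliest observed time at which every mitotic figure is labeled (and
#' remains so at all later observed times): a cell in mitosis t hours after
#' labeling onset was in S at onset only if t exceeds G2+M.
#'
#' @param mitotic_labeling Data frame with columns `time_h` (strictly
#'   increasing) and `fraction_labeled` in \[0, 1\].
#' @return Time in hours.
#' @export
estimate_tg2m <- function(mitotic_labeling) {
  ml <- as.data.frame(mitotic_labeling)
  if (!all(c("time_h", "fraction_labeled") %in% names(ml)))
    stop("need columns 'time_h' and 'fraction_labeled'")
  if (is.unsorted(ml$time_h, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(ml$fraction_labeled < 0 | ml$fraction_labeled > 1))
    stop("fractions must lie in [0, 1]")
  at_one <- ml$fraction_labeled >= 1
  # earliest time from which the curve stays saturated
  ok <- rev(cumprod(rev(at_one))) == 1
  if (!any(ok))
    stop("labeled-mitoses fraction never saturates at 1 (missing-saturation)")
  ml$time_h[which(ok)[1]]
}

#' Extrapolate an observed differentiated fraction to a full cell cycle
#'
#' When only a fraction of the labeled population has completed a full cycle
#' within the chase period, the observed differentiated fraction
#' underestimates per-cycle differentiation. Linear scaling gives
#' f_full = min(1, f_observed / completed_cycle_fraction); the companion
#' value 1 - f_full is the expected stem-marker-retaining fraction.
#'
#' @param f_diff_observed Observed differentiated fraction in \[0, 1\].
#' @param completed_cycle_fraction Fraction of cells that completed a full
#'   cycle during the chase, in (0, 1].
#' @return List with `f_full` and `retained`.
#' @export
extrapolate_full_cycle_differentiation <- function(f_diff_observed,
                                                   completed_cycle_fraction) {
  if (f_diff_observed < 0 || f_diff_observed > 1)
    stop("'f_diff_observed' must lie in [0, 1]")
  if (completed_cycle_fraction <= 0 || completed_cycle_fraction > 1)
    stop("'completed_cycle_fraction' must lie in (0, 1]")
  f_full <- min(1, f_diff_observed / completed_cycle_fraction)
  list(f_full = f_full, retained = 1 - f_full)
}
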