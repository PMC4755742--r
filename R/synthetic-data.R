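#' Agent-based cumulative-labeling simulator
#'
#' Simulates an asynchronously cycling cell population under continuous
#' label availability and reports the labeled fraction among counted cells
#' at each sampling time. Model assumptions mirror the closed-form curve:
#' constant phase lengths (order G1 -> S -> G2M), completely asynchronous
#' divisions, label incorporated by any cell that spends time in S-phase
#' after t = 0 and inherited by all descendants.
#'
#' Initial ages are drawn from the steady-state age density: uniform on
#' \[0, T_C) for r = 1, proportional to r^(-a/T_C) for r = 2. A fraction GF
#' of founder cells is cycling; the rest never divide and stay unlabeled.
#' Because phase lengths are constant, every descendant of a founder shares
#' its label state and cycle position, so lineages are propagated
#' deterministically: a founder of initial age a0 has had
#' k = floor((a0 + t)/T_C) divisions by time t and contributes r^k counted
#' cycling cells (for r = 1 the postmitotic sibling produced at each
#' division is excluded from counting, so the counted weight stays 1).
#'
#' @param params A [cell_cycle_params] object (the ground truth).
#' @param n_cells Number of founder lineages (>= 1000 recommended for
#'   oracle use; a warning is issued below that).
#' @param times Sampling times in hours (>= 0).
#' @param seed Optional integer seed (applied via a local RNG state).
#' @return List with `times`, `labeled_fraction` (per time), `n_lineages`,
#'   `counted_weight` (total counted cells per time), `params`, `seed`.
#' @export
simulate_labeling_experiment <- function(params, n_cells = 1e5,
                                         times = seq(0, 120, by = 12),
                                         seed = NULL) {
  stopifnot(inherits(params, "cell_cycle_params"))
  if (any(times < 0)) stop("sampling times must be non-negative")
  if (n_cells < 1000) warning("fewer than 1000 lineages: oracle precision low")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  T_C <- params$T_C; T_S <- params$T_S; G <- params$T_G2M
  T_G1 <- T_C - T_S - G
  r <- params$r

  n_prolif <- stats::rbinom(1, n_cells, params$GF)
  n_post <- n_cells - n_prolif

  u <- stats::runif(n_prolif)
  a0 <- if (r == 1) u * T_C else
    -T_C * log(1 - u * (1 - 1 / r)) / log(r)

  # hours until the lineage first occupies S-phase (0 if in S at onset)
  t_label <- ifelse(a0 < T_G1, T_G1 - a0,
             ifelse(a0 < T_G1 + T_S, 0, T_C - a0 + T_G1))

  lf <- numeric(length(times))
  wt <- numeric(length(times))
  for (j in seq_along(times)) {
    t <- times[j]
    w <- r^(floor((a0 + t) / T_C))   # counted descendants per lineage
    labeled <- t >= t_label
    wt[j] <- sum(w) + n_post
    lf[j] <- sum(w[labeled]) / wt[j]
  }
  list(times = times, labeled_fraction = lf, n_lineages = n_cells,
       n_proliferative = n_prolif, counted_weight = wt,
       params = params, seed = seed)
}

#' Simulate a replicated labeling timecourse
#'
#' Builds a measurement table of the kind the model fitter consumes: at
#' each sampling time, `n_animals` independent animals are simulated (each
#' an independent agent-based population of `cells_per_animal` founder
#' lineages) and the mean and s.d. of their labeled fractions recorded.
#' The per-animal s.d. is floored at 1e-3 so that plateau timepoints where
#' all animals coincide keep a finite weight.
#'
#' @param params Ground-truth [cell_cycle_params].
#' @param times Sampling grid in hours.
#' @param n_animals Animals per timepoint.
#' @param cells_per_animal Counted founder lineages per animal.
#' @param seed Optional integer seed.
#' @return List with `timecourse` (data frame `time_h`,
#'   `fraction_labeled`, `sd`, `n_animals`) and `truth` (the parameters and
#'   seed).
#' @export
simulate_labeling_timecourse <- function(params, times = seq(0, 120, by = 12),
                                         n_animals = 5,
                                         cells_per_animal = 200,
                                         seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  fr <- replicate(n_animals, {
    suppressWarnings(
      simulate_labeling_experiment(params, n_cells = cells_per_animal,
                                   times = times))$labeled_fraction
  })
  tc <- data.frame(time_h = times,
                   fraction_labeled = rowMeans(fr),
                   sd = pmax(apply(fr, 1, stats::sd), 1e-3),
                   n_animals = n_animals)
  list(timecourse = tc,
       truth = list(params = params, n_animals = n_animals,
                    cells_per_animal = cells_per_animal, seed = seed))
}

# Sample |cos(theta)| for a Watson-type axial density f(u) ~ exp(kappa u^2)
# on [0, 1] by numeric inverse-CDF interpolation (exact uniform at kappa=0).
sample_axial_cos <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n))
  g <- seq(0, 1, length.out = 2048)
  w <- exp(kappa * (g^2 - 1))          # shift by -kappa for overflow safety
  cdf <- cumsum(w); cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  stats::approx(cdf, g, xout = stats::runif(n), ties = "ordered")$y
}

#' Sample synthetic mitotic-spindle orientation measurements
#'
#' Draws `n` division orientations and emits them as pole/axis coordinate
#' records of the form the projection analysis reads. With concentration
#' `kappa = 0` directions are uniform on the unit sphere, so projections on
#' any fixed axis are exactly Uniform(0, 1) (the orientation-test null).
#' With `kappa > 0` directions follow a Watson-type axial density
#' proportional to exp(kappa cos^2 theta) around `axis`, concentrating the
#' projections near 1 as kappa grows.
#'
#' @param n Number of cells.
#' @param kappa Concentration parameter (>= 0).
#' @param axis Length-3 AP-axis direction (need not be unit length).
#' @param seed Optional integer seed.
#' @param spindle_length_um Pole-to-pole distance (default 8).
#' @return Data frame with `cell_id`, pole columns `ax..bz`, axis columns
#'   `cx..dz`, and the true `projection` used to generate each record.
#' @export
sample_spindle_orientations <- function(n, kappa = 0, axis = c(0, 0, 1),
                                        seed = NULL, spindle_length_um = 8) {
  if (n < 1) stop("'n' must be at least 1")
  if (kappa < 0) stop("'kappa' must be non-negative")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  ax <- axis / sqrt(sum(axis^2))

  if (kappa == 0) {
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
  } else {
    u <- sample_axial_cos(n, kappa)            # |cos| to the axis
    cosv <- u * sample(c(-1, 1), n, replace = TRUE)
    sinv <- sqrt(pmax(0, 1 - cosv^2))
    phi <- stats::runif(n, 0, 2 * pi)
    # orthonormal frame around the axis
    e1 <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * ax) * ax; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
            ax[3] * e1[1] - ax[1] * e1[3],
            ax[1] * e1[2] - ax[2] * e1[1])
    v <- outer(cosv, ax) + outer(sinv * cos(phi), e1) +
         outer(sinv * sin(phi), e2)
  }

  centre <- matrix(stats::runif(3 * n, -100, 100), ncol = 3)
  half <- spindle_length_um / 2
  A <- centre - half * v
  B <- centre + half * v
  C <- centre + matrix(stats::runif(3 * n, -5, 5), ncol = 3) - 25 * rep(1, n) %o% ax
  D <- C + 50 * rep(1, n) %o% ax

  out <- data.frame(cell_id = seq_len(n),
                    ax = A[, 1], ay = A[, 2], az = A[, 3],
                    bx = B[, 1], by = B[, 2], bz = B[, 3],
                    cx = C[, 1], cy = C[, 2], cz = C[, 3],
                    dx = D[, 1], dy = D[, 2], dz = D[, 3])
  out$projection <- abs(v %*% ax)[, 1]
  out
}

#' Mean projection of the Watson-type axial family
#'
#' Expected |cos theta| under the density proportional to
#' exp(kappa cos^2 theta); used to choose a concentration that yields a
#' target mean projection (power analyses of [orientation_test]).
#'
#' @param kappa Concentration (>= 0).
#' @return Expected projection in \[0.5, 1).
#' @export
watson_mean_projection <- function(kappa) {
  if (kappa == 0) return(0.5)
  num <- stats::integrate(function(u) u * exp(kappa * (u^2 - 1)), 0, 1)$value
  den <- stats::integrate(function(u) exp(kappa * (u^2 - 1)), 0, 1)$value
  num / den
}

#' Concentration achieving a target mean projection
#'
#' @param target Mean projection in (0.5, 1).
#' @return Concentration kappa.
#' @export
solve_concentration <- function(target) {
  if (target <= 0.5 || target >= 1) stop("'target' must lie in (0.5, 1)")
  stats::uniroot(function(k) watson_mean_projection(k) - target,
                 c(1e-6, 500), tol = 1e-8)$root
}

#' Simulate an nCounter-style count matrix
#'
#' Generates a probes-by-samples count matrix with spike-in positive
#' controls (geometric titration series), negative controls (Poisson
#' background), one housekeeping probe, and endogenous genes with
#' negative-binomially distributed counts. Per-sample technical scale
#' factors are drawn log-normally and multiply every probe, emulating
#' hybridization-efficiency variation that positive-control normalization
#' removes. A chosen number of genes is differentially expressed between
#' the two groups at the given log2 fold change (half up, half down).
#'
#' @param n_genes Endogenous genes.
#' @param n_true_de Number of DE genes (<= n_genes).
#' @param log2fc Absolute log2 fold change of DE genes (group b vs a).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param n_a,n_b Samples per group.
#' @param seed Optional integer seed.
#' @param base_mean_range Log10 range endogenous baseline means are drawn
#'   from (default 50 to 5000).
#' @param positive_means Titration means of the 6 positive probes.
#' @param negative_mean Poisson mean of the 8 negative probes.
#' @param housekeeping_mean Housekeeping probe mean.
#' @param factor_sdlog Log-normal s.d. of the per-sample scale factors.
#' @return List with `counts` (matrix), `probe_class`, `sample_group`, and
#'   `truth` (DE gene ids, directions, scale factors, seed).
#' @export
simulate_nanostring_counts <- function(n_genes = 100, n_true_de = 0,
                                       log2fc = 2, dispersion = 0.05,
                                       n_a = 3, n_b = 3, seed = NULL,
                                       base_mean_range = c(50, 5000),
                                       positive_means = c(8192, 2048, 512,
                                                          128, 32, 8),
                                       negative_mean = 10,
                                       housekeeping_mean = 5000,
                                       factor_sdlog = 0.2) {
  if (n_a < 2 || n_b < 2) stop("need at least 2 samples per group")
  if (n_true_de > n_genes) stop("'n_true_de' cannot exceed 'n_genes'")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n_s <- n_a + n_b
  group <- c(rep("a", n_a), rep("b", n_b))
  sf <- stats::rlnorm(n_s, 0, factor_sdlog)

  base <- 10^stats::runif(n_genes, log10(base_mean_range[1]),
                          log10(base_mean_range[2]))
  de_idx <- if (n_true_de > 0) sample.int(n_genes, n_true_de) else integer(0)
  de_dir <- rep(0L, n_genes)
  if (n_true_de > 0)
    de_dir[de_idx] <- rep_len(c(1L, -1L), n_true_de)

  mu <- matrix(base, n_genes, n_s)
  bsel <- group == "b"
  mu[, bsel] <- mu[, bsel] * 2^(de_dir * log2fc)
  mu <- sweep(mu, 2, sf, `*`)

  size <- 1 / dispersion
  counts_end <- matrix(stats::rnbinom(n_genes * n_s, mu = mu, size = size),
                       n_genes, n_s)
  counts_pos <- matrix(stats::rnbinom(length(positive_means) * n_s,
                                      mu = outer(positive_means, sf),
                                      size = 1 / 0.01),
                       length(positive_means), n_s)
  counts_hk <- matrix(stats::rnbinom(n_s, mu = housekeeping_mean * sf,
                                     size = 1 / 0.01), 1, n_s)
  # non-specific background counts affect every probe; negative-control
  # probes carry background only
  counts <- rbind(counts_end, counts_pos, matrix(0, 8, n_s), counts_hk)
  counts <- counts + matrix(
    stats::rpois(nrow(counts) * n_s, negative_mean * rep(sf, each = nrow(counts))),
    nrow(counts), n_s)
  rownames(counts) <- c(sprintf("gene%03d", seq_len(n_genes)),
                        sprintf("POS_%s", LETTERS[seq_along(positive_means)]),
                        sprintf("NEG_%s", LETTERS[1:8]),
                        "Rpl4")
  colnames(counts) <- sprintf("%s%d", group, c(seq_len(n_a), seq_len(n_b)))
  probe_class <- c(rep("endogenous", n_genes),
                   rep("positive", length(positive_means)),
                   rep("negative", 8), "housekeeping")
  list(counts = counts, probe_class = probe_class, sample_group = group,
       truth = list(de_genes = rownames(counts)[de_idx],
                    de_direction = de_dir[de_idx],
                    log2fc = log2fc, dispersion = dispersion,
                    scale_factors = sf, seed = seed))
}

#' Simulate per-section count tables for the mitotic-index estimator
#'
#' For each replicate, `n_sections` physical sections are generated inside
#' the region. The optical-section count of proliferating cells is
#' Poisson with mean `cells_per_section * l_c / l_s` (the optical slice
#' samples a cell-length-thick slab of the section); the mitotic count over
#' the physical section is Binomial(round(N_P), true_mi) with
#' N_P the thickness-corrected proliferating-cell estimate.
#'
#' @param true_mi Ground-truth mitotic index in \[0, 1\].
#' @param n_replicates Biological replicates.
#' @param n_sections Sections measured per replicate.
#' @param cells_per_section Mean proliferating cells per physical section.
#' @param l_s Section thickness (micrometres).
#' @param l_c Mean AP cell length (micrometres).
#' @param region Length-2 AP bounds of the population (micrometres).
#' @param seed Optional integer seed.
#' @return List with `sections` (data frame `replicate`, `section`,
#'   `ap_position_um`, `n_pcna`, `n_mitotic`, `section_thickness_um`),
#'   `l_c`, `region`, and `truth`.
#' @export
simulate_section_counts <- function(true_mi, n_replicates = 3,
                                    n_sections = 8, cells_per_section = 100,
                                    l_s = 50, l_c = 12.5,
                                    region = c(0, 500), seed = NULL) {
  if (true_mi < 0 || true_mi > 1) stop("'true_mi' must lie in [0, 1]")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  ns_total <- floor((region[2] - region[1]) / l_s)
  if (n_sections > ns_total)
    stop("'n_sections' exceeds the number of sections in the region")
  rows <- lapply(seq_len(n_replicates), function(i) {
    pos <- region[1] + (sort(sample.int(ns_total, n_sections)) - 0.5) * l_s
    n_pcna <- stats::rpois(n_sections, cells_per_section * l_c / l_s)
    n_p <- round(n_pcna * l_s / l_c)
    n_m <- stats::rbinom(n_sections, n_p, true_mi)
    data.frame(replicate = i, section = seq_len(n_sections),
               ap_position_um = pos, n_pcna = n_pcna, n_mitotic = n_m,
               section_thickness_um = l_s)
  })
  list(sections = do.call(rbind, rows), l_c = l_c, region = region,
       truth = list(true_mi = true_mi, seed = seed))
}
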