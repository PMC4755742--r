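#' Proliferating cells per physical section
#'
#' Proliferating (SOX2+PCNA+) cells are counted in a single optical
#' cross-section, while mitotic figures are counted through the full
#' physical section. To put both on the same footing the optical count is
#' scaled by the ratio of section thickness to mean cell length along the
#' anterior-posterior axis: N_P = N_PCNA * l_s / l_c.
#'
#' @param n_pcna Optical-section count of proliferating cells (>= 0).
#' @param l_s Physical section thickness, micrometres (> 0).
#' @param l_c Mean AP cell (nucleus) length, micrometres (> 0).
#' @return Estimated proliferating cells in the physical section.
#' @export
proliferating_cells_per_section <- function(n_pcna, l_s, l_c) {
  if (any(l_s <= 0) || any(l_c <= 0)) stop("'l_s' and 'l_c' must be positive")
  if (any(n_pcna < 0)) stop("'n_pcna' must be non-negative")
  n_pcna * l_s / l_c
}

#' Per-section mitotic index
#'
#' mi = N_M / N_P, the fraction of proliferating cells in M-phase in one
#' section. Sections with no proliferating cells cannot form an index: with
#' N_M = 0 too they are flagged for exclusion (`NA` returned), with
#' N_M > 0 the input is inconsistent and an error is raised.
#'
#' @param n_mitotic Mitotic cells in the physical section (>= 0).
#' @param n_p Proliferating cells in the physical section (see
#'   [proliferating_cells_per_section]).
#' @return Mitotic index (or `NA` for an excluded empty section).
#' @export
section_mitotic_index <- function(n_mitotic, n_p) {
  if (any(n_mitotic < 0)) stop("'n_mitotic' must be non-negative")
  out <- numeric(length(n_mitotic))
  empty <- n_p == 0
  if (any(empty & n_mitotic > 0))
    stop("mitotic cells found in a section with no proliferating cells")
  out[empty] <- NA_real_
  out[!empty] <- n_mitotic[!empty] / n_p[!empty]
  out
}

#' Replicate-level mitotic index with finite-population error
#'
#' Averages the per-section mitotic indices of one biological replicate and
#' attaches the standard error of the mean with finite population size
#' correction,
#' \deqn{\Delta mi = \sqrt{\frac{n_s^{total} - n_s}{n_s^{total} - 1}}
#'   \frac{\sigma_i}{\sqrt{n_s}},}
#' where \eqn{n_s} is the number of sections measured, \eqn{\sigma_i} their
#' standard deviation and \eqn{n_s^{total} = (l_{max} - l_{min})/l_s} the
#' total number of sections spanning the region under study (rounded to the
#' nearest integer, with a warning when the ratio is not integral). When
#' every section was measured the correction vanishes and the error is 0.
#'
#' @param sections Data frame for one replicate with columns `n_pcna`,
#'   `n_mitotic`, `ap_position_um` and `section_thickness_um`.
#' @param l_min,l_max AP bounds of the region (micrometres, `l_max > l_min`).
#' @param l_c Mean AP cell length for this replicate (micrometres).
#' @return List with `mi`, `dmi`, `n_sections`, `ns_total`, `n_excluded`,
#'   `n1_flag` (single usable section, error undefined and set `NA`).
#' @export
replicate_mitotic_index <- function(sections, l_min, l_max, l_c) {
  sec <- as.data.frame(sections)
  need <- c("n_pcna", "n_mitotic", "ap_position_um", "section_thickness_um")
  miss <- setdiff(need, names(sec))
  if (length(miss)) stop("sections missing column(s): ",
                         paste(miss, collapse = ", "))
  if (l_max <= l_min) stop("'l_max' must exceed 'l_min'")
  sec <- sec[sec$ap_position_um >= l_min & sec$ap_position_um <= l_max, ]
  if (nrow(sec) == 0L) stop("no sections inside the region")
  l_s <- unique(sec$section_thickness_um)
  if (length(l_s) != 1L) stop("sections of one replicate must share thickness")

  ratio <- (l_max - l_min) / l_s
  ns_total <- round(ratio)
  if (abs(ratio - ns_total) > 1e-8)
    warning("region length is not an integer multiple of section thickness; ",
            "ns_total rounded to ", ns_total)

  n_p <- proliferating_cells_per_section(sec$n_pcna, l_s, l_c)
  mi_sec <- section_mitotic_index(sec$n_mitotic, n_p)
  n_excluded <- sum(is.na(mi_sec))
  mi_sec <- mi_sec[!is.na(mi_sec)]
  ns <- length(mi_sec)
  if (ns == 0L) stop("no usable sections (all had zero proliferating cells)")
  if (ns > ns_total) stop("more sections measured than fit in the region")

  mi <- mean(mi_sec)
  if (ns == 1L) {
    dmi <- NA_real_
  } else if (ns == ns_total) {
    dmi <- 0
  } else {
    fpc <- sqrt((ns_total - ns) / (ns_total - 1))
    dmi <- fpc * stats::sd(mi_sec) / sqrt(ns)
  }
  list(mi = mi, dmi = dmi, n_sections = ns, ns_total = ns_total,
       n_excluded = n_excluded, n1_flag = ns == 1L)
}

#' Population mitotic index across biological replicates
#'
#' The population mitotic index is the mean of the replicate indices. Its
#' 1-sigma error adds the mean intra-replicate error and the
#' inter-replicate standard error: \eqn{\Delta mi = \overline{\Delta mi_i}
#' + \sigma/\sqrt{n}} with \eqn{\sigma} the s.d. of the replicate means.
#' This additive combination is deliberate (it matches the error model used
#' for the original measurements); `combine = "quadrature"` gives the
#' conventional root-sum-of-squares alternative for sensitivity analysis.
#'
#' @param replicates List of results from [replicate_mitotic_index] (or any
#'   lists with `mi` and `dmi` entries).
#' @param combine `"additive"` (default) or `"quadrature"`.
#' @return List of class `mitotic_index_result` with `mi`, `dmi`,
#'   `n_replicates`, `replicate_mi`, `replicate_dmi`, `n1_flag`.
#' @export
population_mitotic_index <- function(replicates, combine = c("additive",
                                                             "quadrature")) {
  combine <- match.arg(combine)
  if (length(replicates) == 0L) stop("need at least one replicate")
  mi_i <- vapply(replicates, function(r) r$mi, numeric(1))
  dmi_i <- vapply(replicates, function(r) r$dmi, numeric(1))
  n <- length(mi_i)
  mi <- mean(mi_i)
  if (n == 1L) {
    dmi <- dmi_i[1]
  } else {
    intra <- mean(dmi_i, na.rm = TRUE)
    if (is.nan(intra)) intra <- 0
    inter <- stats::sd(mi_i) / sqrt(n)
    dmi <- if (combine == "additive") intra + inter
           else sqrt(intra^2 + inter^2)
  }
  structure(list(mi = mi, dmi = dmi, n_replicates = n,
                 replicate_mi = mi_i, replicate_dmi = dmi_i,
                 n1_flag = n == 1L),
            class = "mitotic_index_result")
}

#' @export
print.mitotic_index_result <- function(x, ...) {
  cat(sprintf("Mitotic index: %.4f +/- %.4f (n = %d replicates)\n",
              x$mi, x$dmi, x$n_replicates))
  invisible(x)
}

#' Areal mitotic density from whole mounts
#'
#' For whole-mount preparations the mitotic index is expressed as PH3+
#' cells per unit area of the maximum-intensity projection.
#'
#' @param ph3_count Number of PH3+ cells (>= 0).
#' @param area_um2 Projected area in square micrometres (> 0).
#' @return Density in cells per square micrometre.
#' @export
areal_mitotic_density <- function(ph3_count, area_um2) {
  if (any(area_um2 <= 0)) stop("'area_um2' must be positive")
  if (any(ph3_count < 0)) stop("'ph3_count' must be non-negative")
  ph3_count / area_um2
}
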