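unit_vec <- function(p, q, what) {
  v <- as.numeric(q) - as.numeric(p)
  n <- sqrt(sum(v^2))
  if (n == 0) stop("coincident points: cannot form the ", what, " vector")
  v / n
}

#' Spindle projection on the anterior-posterior axis
#'
#' The mitotic-spindle vector S is the unit vector between the two spindle
#' poles A and B; the AP-axis vector is the unit vector between two points
#' C and D placed in the middle of the central canal at the two ends of the
#' image stack. The projection is the absolute scalar product |S . AP|: 1
#' for divisions parallel to the AP axis, 0 for orthogonal divisions. The
#' absolute value makes the statistic independent of the arbitrary pole and
#' axis-point ordering, and for uniformly random 3D orientations it is
#' exactly Uniform(0, 1) — the null of [orientation_test].
#'
#' @param A,B Numeric length-3 coordinates of the spindle poles (micrometres).
#' @param C,D Numeric length-3 coordinates defining the AP axis.
#' @return Projection value in \[0, 1\].
#' @export
spindle_projection <- function(A, B, C, D) {
  S <- unit_vec(A, B, "spindle")
  AP <- unit_vec(C, D, "AP-axis")
  min(1, abs(sum(S * AP)))
}

#' Spindle projections for a table of measurements
#'
#' Vectorized wrapper of [spindle_projection] over a coordinate table.
#'
#' @param cells Data frame with pole columns `ax, ay, az, bx, by, bz` and
#'   axis columns `cx, cy, cz, dx, dy, dz`.
#' @return The input with a `projection` column appended.
#' @export
spindle_projections <- function(cells) {
  cells <- as.data.frame(cells)
  need <- as.vector(outer(c("a", "b", "c", "d"), c("x", "y", "z"), paste0))
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("missing coordinate column(s): ",
                         paste(miss, collapse = ", "))
  cells$projection <- vapply(seq_len(nrow(cells)), function(i) {
    spindle_projection(unlist(cells[i, c("ax", "ay", "az")]),
                       unlist(cells[i, c("bx", "by", "bz")]),
                       unlist(cells[i, c("cx", "cy", "cz")]),
                       unlist(cells[i, c("dx", "dy", "dz")]))
  }, numeric(1))
  cells
}

#' Assign a cell to an AP zone
#'
#' Inside means within the closed interval \[l_min, l_max\] of AP positions
#' (micrometres; negative values are anterior to the amputation plane).
#' Boundary positions count as inside.
#'
#' @param ap_position_um AP position(s) of the cell(s).
#' @param zone_bounds Length-2 numeric `(l_min, l_max)`.
#' @return Logical vector, `TRUE` for inside.
#' @export
assign_zone <- function(ap_position_um, zone_bounds) {
  if (length(zone_bounds) != 2L || zone_bounds[2] < zone_bounds[1])
    stop("'zone_bounds' must be an ordered pair (l_min, l_max)")
  ap_position_um >= zone_bounds[1] & ap_position_um <= zone_bounds[2]
}

#' Test whether divisions are oriented along the AP axis
#'
#' Under the null of randomly oriented divisions the projections are
#' Uniform(0, 1) with mean 0.5 and standard deviation 1/sqrt(12). For N
#' cells the observed mean projection lies below
#' 0.5 + 1.96/sqrt(12 N) with probability 0.975, so divisions are declared
#' oriented when the mean exceeds that threshold (one-sided, nominal level
#' 0.025, normal approximation; no small-N correction is applied).
#'
#' @param projections Numeric vector of projection values in \[0, 1\].
#' @return List of class `orientation_test` with `n`, `mean_projection`,
#'   `threshold`, `oriented`, `level`.
#' @export
orientation_test <- function(projections) {
  p <- as.numeric(projections)
  if (length(p) == 0L) stop("'projections' must be non-empty")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("projections must lie in [0, 1]")
  n <- length(p)
  thr <- 0.5 + 1.96 / sqrt(12 * n)
  structure(list(n = n, mean_projection = mean(p), threshold = thr,
                 oriented = mean(p) > thr, level = 0.025),
            class = "orientation_test")
}

#' @export
print.orientation_test <- function(x, ...) {
  cat(sprintf(
    "Orientation test: N = %d, mean projection = %.4f, threshold = %.4f\n",
    x$n, x$mean_projection, x$threshold))
  cat(sprintf("  divisions %s oriented along the AP axis (one-sided, p < %.3f)\n",
              if (x$oriented) "ARE" else "are NOT significantly", x$level))
  invisible(x)
}

#' Cleavage-plane angle from a 2D longitudinal section
#'
#' The cleavage plane is orthogonal to the mitotic spindle; in a 2D optical
#' section its direction is the spindle direction rotated by 90 degrees.
#' The reported angle is the acute angle between that cleavage direction
#' and the apical surface of the spinal cord, folded to \[0, 90\] degrees:
#' 90 for a spindle parallel to the apical surface ("vertical" cleavage,
#' symmetric division geometry), 0 for a spindle orthogonal to it.
#'
#' @param s1,s2 Length-2 coordinates of the spindle endpoints (micrometres).
#' @param a1,a2 Length-2 coordinates of two points on the apical surface.
#' @return Angle in degrees in \[0, 90\].
#' @export
cleavage_angle <- function(s1, s2, a1, a2) {
  s <- unit_vec(s1, s2, "spindle")
  ap <- unit_vec(a1, a2, "apical-surface")
  cleave <- c(-s[2], s[1])  # spindle rotated 90 degrees in-plane
  # acute angle between the cleavage line and the apical line
  acos(min(1, abs(sum(cleave * ap)))) * 180 / pi
}

#' Compare two cleavage-angle distributions
#'
#' Rank-based two-group comparison via [mann_whitney_u], with per-group
#' location and spread summaries (median, interquartile range, s.d.).
#'
#' @param angles_a,angles_b Non-empty numeric vectors of angles in degrees.
#' @return List with `U`, `p`, `method` and a `summary` data frame.
#' @export
compare_angle_distributions <- function(angles_a, angles_b) {
  mw <- mann_whitney_u(angles_a, angles_b)
  summ <- function(x) c(n = length(x), median = stats::median(x),
                        iqr = stats::IQR(x),
                        sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  list(U = mw$U, p = mw$p, method = mw$method,
       summary = as.data.frame(rbind(a = summ(angles_a),
                                     b = summ(angles_b))))
}
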