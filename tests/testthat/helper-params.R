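# Random valid cell-cycle parameter sets for property tests.
random_params <- function(n, r = NULL) {
  lapply(seq_len(n), function(i) {
    T_C <- stats::runif(1, 50, 400)
    T_S <- stats::runif(1, 0.1, 0.5) * T_C
    T_G2M <- stats::runif(1, 0.02, 0.15) * T_C
    if (T_S + T_G2M >= T_C) T_G2M <- 0.9 * (T_C - T_S)
    cell_cycle_params(T_C = T_C, T_S = T_S, T_G2M = T_G2M,
                      GF = stats::runif(1, 0.5, 1),
                      r = if (is.null(r)) sample(c(1, 2), 1) else r)
  })
}

# Exact two-sided Fisher p by hypergeometric enumeration over all tables
# with the observed margins (point-probability convention, with the usual
# relative tolerance for floating-point ties).
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  if (N == 0) return(1)
  ks <- max(0, r1 + c1 - N):min(r1, c1)
  pr <- stats::dhyper(ks, c1, N - c1, r1)
  obs <- stats::dhyper(a, c1, N - c1, r1)
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments
# of the pooled (tie-free) values.
mw_enum_p <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  vals <- c(a, b)
  rk <- rank(vals)
  u_obs <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  subsets <- utils::combn(n_a + n_b, n_a)
  u_all <- apply(subsets, 2, function(s) sum(rk[s])) - n_a * (n_a + 1) / 2
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}
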