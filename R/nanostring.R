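#' Construct an nCounter-style count matrix object
#'
#' Light container for probes-by-samples counts with per-probe class
#' annotations (`endogenous`, `positive`, `negative`, `housekeeping`) and
#' per-sample group labels.
#'
#' @param counts Numeric matrix (probes x samples), non-negative, with
#'   probe row names and sample column names.
#' @param probe_class Character vector, one class per probe.
#' @param sample_group Character vector, one group label per sample.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, probe_class, sample_group) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  if (length(probe_class) != nrow(counts))
    stop("'probe_class' must have one entry per probe")
  if (length(sample_group) != ncol(counts))
    stop("'sample_group' must have one entry per sample")
  ok <- c("endogenous", "positive", "negative", "housekeeping")
  if (!all(probe_class %in% ok))
    stop("probe classes must be among: ", paste(ok, collapse = ", "))
  if (sum(probe_class == "positive") < 2L ||
      sum(probe_class == "negative") < 2L)
    stop("need at least 2 positive and 2 negative control probes")
  if (sum(probe_class == "housekeeping") < 1L)
    stop("need at least one housekeeping probe")
  structure(list(counts = counts, probe_class = probe_class,
                 sample_group = sample_group),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("nCounter count matrix: %d probes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$probe_class))
  invisible(x)
}

#' Positive-control normalization
#'
#' Scales each sample so the geometric mean of its spike-in positive
#' control probes equals the across-sample arithmetic mean of those
#' geometric means: factor_s = mean(geomeans) / geomean_s. Corrects for
#' technical variation in hybridization and purification efficiency.
#'
#' @param x A [count_matrix].
#' @return List with `matrix` (normalized [count_matrix]) and `factors`
#'   (per-sample scale factors).
#' @export
positive_control_normalize <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  pos <- x$counts[x$probe_class == "positive", , drop = FALSE]
  if (any(pos <= 0)) stop("all positive-control counts must be positive")
  gm <- apply(pos, 2, geometric_mean)
  factors <- mean(gm) / gm
  out <- x
  out$counts <- sweep(x$counts, 2, factors, `*`)
  list(matrix = out, factors = factors)
}

#' Detection call against the negative-control probes
#'
#' For each endogenous (and housekeeping) gene, a one-tailed pooled-variance
#' t-test compares the gene's counts across the given samples with the
#' pooled negative-control counts of the same samples. Genes with
#' p >= 0.05 are called absent; their counts are blanketed to 1 downstream.
#'
#' @param x A [count_matrix] (typically positive-control normalized).
#' @param samples Optional sample index/name subset (default all).
#' @param alpha Detection level (default 0.05).
#' @return Data frame with `probe`, `p`, `present`.
#' @export
detection_call <- function(x, samples = NULL, alpha = 0.05) {
  stopifnot(inherits(x, "count_matrix"))
  cts <- x$counts
  if (!is.null(samples)) cts <- cts[, samples, drop = FALSE]
  if (ncol(cts) < 2L) stop("need at least 2 samples for the detection test")
  neg <- as.vector(cts[x$probe_class == "negative", , drop = FALSE])
  test_rows <- which(x$probe_class %in% c("endogenous", "housekeeping"))
  p <- vapply(test_rows, function(i) one_tailed_t_test(cts[i, ], neg),
              numeric(1))
  data.frame(probe = rownames(cts)[test_rows], p = p,
             present = p < alpha, row.names = NULL)
}

#' Background subtraction
#'
#' Subtracts, per sample, the mean plus three standard deviations of that
#' sample's negative-control probes from every present gene's counts,
#' flooring at 1; genes called absent are set to 1 in all samples. (Pooled
#' background across samples is available via `per_sample = FALSE`.)
#'
#' @param x A [count_matrix].
#' @param flags Data frame from [detection_call].
#' @param per_sample Compute background per sample (default) or pooled.
#' @return A background-corrected [count_matrix].
#' @export
background_subtract <- function(x, flags, per_sample = TRUE) {
  stopifnot(inherits(x, "count_matrix"))
  cts <- x$counts
  neg <- cts[x$probe_class == "negative", , drop = FALSE]
  bg <- if (per_sample) {
    apply(neg, 2, mean) + 3 * apply(neg, 2, stats::sd)
  } else {
    rep(mean(neg) + 3 * stats::sd(as.vector(neg)), ncol(cts))
  }
  rows <- which(x$probe_class %in% c("endogenous", "housekeeping"))
  idx <- match(rownames(cts)[rows], flags$probe)
  if (anyNA(idx)) stop("detection flags do not cover all tested probes")
  present <- flags$present[idx]
  sub <- sweep(cts[rows, , drop = FALSE], 2, bg, `-`)
  sub[sub < 1] <- 1
  sub[!present, ] <- 1
  out <- x
  out$counts[rows, ] <- sub
  out
}

#' Housekeeping normalization
#'
#' Scales each sample so its housekeeping counts (geometric mean across
#' housekeeping probes if several) equal the across-sample mean, correcting
#' for input-material variation.
#'
#' @param x A [count_matrix].
#' @return List with `matrix` and per-sample `factors`.
#' @export
housekeeping_normalize <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  hk <- x$counts[x$probe_class == "housekeeping", , drop = FALSE]
  if (any(hk <= 0)) stop("housekeeping counts must be positive in all samples")
  hv <- apply(hk, 2, geometric_mean)
  factors <- mean(hv) / hv
  out <- x
  out$counts <- sweep(x$counts, 2, factors, `*`)
  list(matrix = out, factors = factors)
}

#' Full nCounter normalization chain
#'
#' Runs, in order: positive-control normalization, detection calling
#' against negative controls, background subtraction with blanketing to 1,
#' and housekeeping normalization — yielding counts ready for differential
#' expression analysis.
#'
#' @param x A raw [count_matrix].
#' @param samples Optional sample subset used for detection and returned.
#' @param per_sample_background See [background_subtract].
#' @return List with `matrix` (normalized), `positive_factors`,
#'   `housekeeping_factors`, `detection` (flag table).
#' @export
normalize_ncounter <- function(x, samples = NULL,
                               per_sample_background = TRUE) {
  stopifnot(inherits(x, "count_matrix"))
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, colnames(x$counts))
           else samples
    x$counts <- x$counts[, idx, drop = FALSE]
    x$sample_group <- x$sample_group[idx]
  }
  pn <- positive_control_normalize(x)
  flags <- detection_call(pn$matrix)
  bs <- background_subtract(pn$matrix, flags,
                            per_sample = per_sample_background)
  hn <- housekeeping_normalize(bs)
  list(matrix = hn$matrix, positive_factors = pn$factors,
       housekeeping_factors = hn$factors, detection = flags)
}

# Per-gene NB dispersion: method-of-moments on within-group variances,
# shrunk toward a parametric mean-dispersion trend alpha(mu) = a0 + a1/mu
# by taking the larger of the two (conservative with n = 3 per group).
estimate_dispersions <- function(mat_a, mat_b) {
  mu <- (rowMeans(mat_a) + rowMeans(mat_b)) / 2
  v <- (apply(mat_a, 1, stats::var) + apply(mat_b, 1, stats::var)) / 2
  alpha_raw <- pmax((v - mu) / mu^2, 0)
  keep <- mu > 0 & is.finite(alpha_raw)
  a <- c(0, 0)
  if (sum(keep) >= 3L) {
    fit <- tryCatch(
      stats::lm(alpha_raw[keep] ~ I(1 / mu[keep])),
      error = function(e) NULL)
    if (!is.null(fit)) a <- pmax(stats::coef(fit), 0)
  }
  alpha_trend <- a[1] + a[2] / pmax(mu, 1)
  pmax(pmax(alpha_raw, alpha_trend), 1e-8)
}

# Exact conditional two-group NB test: conditional on the two group totals
# summing to K, p is the probability of splits as or less likely than the
# observed one. Group sums of iid NB(mu, alpha) are NB(n mu, alpha / n).
nb_exact_test_one <- function(ka, kb, n_a, n_b, alpha) {
  K <- ka + kb
  if (K == 0) return(1)
  mu <- K / (n_a + n_b)
  ks <- 0:K
  pa <- stats::dnbinom(ks, mu = n_a * mu, size = n_a / alpha)
  pb <- stats::dnbinom(K - ks, mu = n_b * mu, size = n_b / alpha)
  pr <- pa * pb
  tot <- sum(pr)
  if (tot == 0) return(1)
  obs <- pr[ka + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-8)]) / tot)
}

#' Negative-binomial differential expression test
#'
#' Two-group exact conditional negative-binomial test per endogenous gene
#' on normalized counts. Count sums per group are modeled as negative
#' binomial with a common per-gene dispersion estimated by the method of
#' moments and shrunk toward a fitted mean-dispersion trend
#' alpha(mu) = a0 + a1/mu; the p-value sums the probabilities of all
#' splits of the two-group total that are no more likely than the observed
#' split. Fold changes are log2(mean_b / mean_a) with group means floored
#' at 1, so a gene blanketed to 1 everywhere has log2FC = 0. Raw p < 0.05
#' flags significance; BH-adjusted p-values are reported alongside.
#'
#' @param x A normalized [count_matrix].
#' @param group_a,group_b Group labels (in `x$sample_group`) to compare;
#'   fold change is b over a.
#' @param alpha_sig Raw-p significance threshold (default 0.05).
#' @return Data frame of class `de_result`: `gene`, `mean_a`, `mean_b`,
#'   `log2fc`, `p`, `padj`, `significant`, `direction` (`up`/`down`/`ns`).
#' @export
nb_differential_test <- function(x, group_a, group_b, alpha_sig = 0.05) {
  stopifnot(inherits(x, "count_matrix"))
  sel_a <- x$sample_group == group_a
  sel_b <- x$sample_group == group_b
  if (sum(sel_a) < 2L || sum(sel_b) < 2L)
    stop("need at least 2 replicates per group")
  rows <- x$probe_class == "endogenous"
  # integer counts for the exact test; normalization yields fractional
  # values, rounding keeps the conditional distribution well-defined
  mat_a <- round(x$counts[rows, sel_a, drop = FALSE])
  mat_b <- round(x$counts[rows, sel_b, drop = FALSE])
  disp <- estimate_dispersions(mat_a, mat_b)
  n_a <- ncol(mat_a); n_b <- ncol(mat_b)
  p <- vapply(seq_len(nrow(mat_a)), function(i) {
    nb_exact_test_one(sum(mat_a[i, ]), sum(mat_b[i, ]), n_a, n_b, disp[i])
  }, numeric(1))
  mean_a <- pmax(rowMeans(mat_a), 1)
  mean_b <- pmax(rowMeans(mat_b), 1)
  log2fc <- log2(mean_b / mean_a)
  padj <- bh_adjust(p)$adjusted_p
  sig <- p < alpha_sig
  direction <- ifelse(!sig | log2fc == 0, "ns",
                      ifelse(log2fc > 0, "up", "down"))
  res <- data.frame(gene = rownames(x$counts)[rows],
                    mean_a = mean_a, mean_b = mean_b, log2fc = log2fc,
                    p = p, padj = padj, significant = sig & log2fc != 0,
                    direction = direction, row.names = NULL)
  class(res) <- c("de_result", class(res))
  res
}

#' Concordance with a developmental reference gene set
#'
#' Compares regeneration differential-expression calls at two timepoints
#' with the direction each gene takes during embryonic neural development
#' (reference classes `low_in_SZPNT` / `high_in_SZPNT`, i.e. genes that go
#' down / up as tissue reverts toward the stem-zone state). A
#' development-low gene is concordant if significantly down at either
#' timepoint; a development-high gene if significantly up at either. The
#' association between reference class and concordance is tested with
#' Fisher's exact test on the resulting 2x2 table.
#'
#' @param de_1,de_2 `de_result` tables (e.g. day 1 and day 6 vs day 0).
#' @param reference Data frame with columns `gene` and `direction`
#'   (`low_in_SZPNT` or `high_in_SZPNT`).
#' @return List with `n_down_concordant`, `n_low_total`,
#'   `n_up_concordant`, `n_high_total`, `table` (2x2), `fisher_p`,
#'   `unmatched` (reference genes absent from the DE tables).
#' @export
concordance_analysis <- function(de_1, de_2, reference) {
  ref <- as.data.frame(reference)
  if (!all(c("gene", "direction") %in% names(ref)))
    stop("reference needs columns 'gene' and 'direction'")
  if (!all(ref$direction %in% c("low_in_SZPNT", "high_in_SZPNT")))
    stop("reference directions must be 'low_in_SZPNT' or 'high_in_SZPNT'")
  unmatched <- setdiff(ref$gene, intersect(de_1$gene, de_2$gene))
  if (length(unmatched))
    warning("excluding reference gene(s) missing from DE results: ",
            paste(unmatched, collapse = ", "))
  ref <- ref[!(ref$gene %in% unmatched), ]

  call_of <- function(de, genes, dir) {
    i <- match(genes, de$gene)
    de$significant[i] & de$direction[i] == dir
  }
  low <- ref$gene[ref$direction == "low_in_SZPNT"]
  high <- ref$gene[ref$direction == "high_in_SZPNT"]
  down_conc <- call_of(de_1, low, "down") | call_of(de_2, low, "down")
  up_conc <- call_of(de_1, high, "up") | call_of(de_2, high, "up")

  tab <- matrix(c(sum(down_conc), length(low) - sum(down_conc),
                  sum(up_conc), length(high) - sum(up_conc)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("low_in_SZPNT", "high_in_SZPNT"),
                                c("concordant", "not_concordant")))
  list(n_down_concordant = sum(down_conc), n_low_total = length(low),
       n_up_concordant = sum(up_conc), n_high_total = length(high),
       table = tab, fisher_p = fisher_exact_2x2(tab),
       unmatched = unmatched)
}

#' Volcano-plot table
#'
#' Derived per-gene columns for a volcano display: log2 fold change,
#' -log10 p, significance class and mean counts. No quantity is
#' recomputed.
#'
#' @param de A `de_result` table.
#' @return Data frame with `gene`, `log2fc`, `neg_log10_p`, `class`,
#'   `mean_counts`.
#' @export
volcano_table <- function(de) {
  data.frame(gene = de$gene, log2fc = de$log2fc,
             neg_log10_p = -log10(pmax(de$p, .Machine$double.xmin)),
             class = de$direction,
             mean_counts = (de$mean_a + de$mean_b) / 2)
}
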