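# Small hand-checkable matrix: 3 endogenous genes, 2 positives, 2 negatives,
# 1 housekeeping probe, 4 samples in two groups.
toy_matrix <- function(scale = c(1, 1, 1, 1)) {
  cts <- rbind(
    geneA = c(400, 440, 80, 90),
    geneB = c(200, 210, 205, 195),
    geneC = c(10, 11, 10, 12),       # near background: should be absent
    POS_A = c(1000, 1000, 1000, 1000),
    POS_B = c(250, 250, 250, 250),
    NEG_A = c(10, 9, 11, 10),
    NEG_B = c(10, 11, 9, 10),
    Rpl4  = c(500, 500, 500, 500))
  cts <- sweep(cts, 2, scale, `*`)
  colnames(cts) <- c("a1", "a2", "b1", "b2")
  count_matrix(cts,
               c("endogenous", "endogenous", "endogenous", "positive",
                 "positive", "negative", "negative", "housekeeping"),
               c("a", "a", "b", "b"))
}

test_that("positive-control factors undo per-sample technical scaling", {
  x <- toy_matrix()
  r <- positive_control_normalize(x)
  expect_equal(unname(r$factors), rep(1, 4))

  x2 <- toy_matrix(scale = c(1, 1, 2, 1))
  r2 <- positive_control_normalize(x2)
  # the doubled sample is scaled down relative to the others by factor 2
  expect_equal(unname(r2$factors[1] / r2$factors[3]), 2)
  # hand oracle: factor_s = mean(geomeans) / geomean_s
  gm <- apply(x2$counts[x2$probe_class == "positive", ], 2,
              function(v) exp(mean(log(v))))
  expect_equal(r2$factors, mean(gm) / gm)
  # normalized positives are identical across samples again
  pos <- r2$matrix$counts[x2$probe_class == "positive", ]
  expect_equal(pos[, 1], pos[, 3])
})

test_that("detection calls separate expressed genes from background", {
  x <- toy_matrix()
  fl <- detection_call(x)
  expect_true(fl$present[fl$probe == "geneA"])
  expect_true(fl$present[fl$probe == "geneB"])
  expect_false(fl$present[fl$probe == "geneC"])
  # a gene equal to the negative-control mean is absent
  cts <- x$counts
  cts["geneA", ] <- c(10, 10, 10, 10)
  x3 <- count_matrix(cts, x$probe_class, x$sample_group)
  expect_false(detection_call(x3)$present[1])
})

test_that("background subtraction floors at 1 and blankets absent genes", {
  x <- toy_matrix()
  fl <- detection_call(x)
  bs <- background_subtract(x, fl, per_sample = FALSE)
  neg <- as.vector(x$counts[x$probe_class == "negative", ])
  bg <- mean(neg) + 3 * sd(neg)
  expect_equal(bs$counts["geneA", 1], 400 - bg)
  expect_equal(unname(bs$counts["geneC", ]), rep(1, 4))   # blanketed
  # counts falling below 1 are floored
  cts <- x$counts
  cts["geneB", ] <- c(30, 31, 30, 32)
  x2 <- count_matrix(cts, x$probe_class, x$sample_group)
  fl2 <- detection_call(x2)
  fl2$present[fl2$probe == "geneB"] <- TRUE
  bs2 <- background_subtract(x2, fl2, per_sample = FALSE)
  bg2 <- mean(neg) + 3 * sd(neg)
  expect_equal(unname(bs2$counts["geneB", ]),
               pmax(c(30, 31, 30, 32) - bg2, 1))
})

test_that("housekeeping normalization equalizes the housekeeping probe", {
  x <- toy_matrix()
  r <- housekeeping_normalize(x)
  expect_equal(unname(r$factors), rep(1, 4))
  x2 <- toy_matrix(scale = c(1, 1, 1, 2))
  r2 <- housekeeping_normalize(x2)
  expect_equal(unname(r2$matrix$counts["Rpl4", ]),
               rep(mean(c(500, 500, 500, 1000)), 4))
  expect_equal(unname(r2$factors[4]), unname(r2$factors[1]) / 2)
})

test_that("the normalization chain fixes an already-normalized matrix", {
  # a background-free matrix with equal controls across samples is a fixed
  # point: every factor is 1 and no background is subtracted (a nonzero
  # background is subtracted anew on each pass, so only the zero-background
  # state can be stationary)
  cts <- rbind(geneA = c(400, 440, 80, 90),
               geneB = c(200, 210, 205, 195),
               POS_A = rep(1000, 4), POS_B = rep(250, 4),
               NEG_A = rep(0, 4), NEG_B = rep(0, 4),
               Rpl4 = rep(500, 4))
  colnames(cts) <- c("a1", "a2", "b1", "b2")
  x <- count_matrix(cts, c("endogenous", "endogenous", "positive",
                           "positive", "negative", "negative",
                           "housekeeping"), c("a", "a", "b", "b"))
  n1 <- normalize_ncounter(x)
  expect_equal(unname(n1$positive_factors), rep(1, 4))
  expect_equal(unname(n1$housekeeping_factors), rep(1, 4))
  expect_equal(n1$matrix$counts, x$counts)
  n2 <- normalize_ncounter(n1$matrix)
  expect_equal(n2$matrix$counts, n1$matrix$counts)
})

test_that("rescaling a sample is undone up to a common factor", {
  # technical rescaling of one lane must not change relative expression:
  # after the full chain, per-probe between-sample ratios are restored and
  # only a global factor (the shifted normalization target) differs
  n_ref <- normalize_ncounter(toy_matrix())
  n_scaled <- normalize_ncounter(toy_matrix(scale = c(1, 3, 1, 1)))
  keep <- rownames(n_ref$matrix$counts) != "geneC"  # blanketed in both
  ratio <- n_scaled$matrix$counts[keep, ] / n_ref$matrix$counts[keep, ]
  expect_lt(diff(range(ratio)), 1e-10)
  # the blanketed gene sits at 1 before the housekeeping step, so it ends
  # at the housekeeping factors, identically in both runs
  expect_equal(unname(n_scaled$matrix$counts["geneC", ]),
               unname(n_scaled$housekeeping_factors))
  expect_equal(n_scaled$matrix$counts["geneC", ],
               n_ref$matrix$counts["geneC", ])
})

test_that("NB test calls obvious differences and ignores identical groups", {
  x <- toy_matrix()
  nm <- normalize_ncounter(x)
  de <- nb_differential_test(nm$matrix, "a", "b")
  expect_equal(de$gene, c("geneA", "geneB", "geneC"))
  gA <- de[de$gene == "geneA", ]
  expect_lt(gA$p, 0.05)
  expect_equal(gA$direction, "down")
  expect_lt(gA$log2fc, 0)
  gB <- de[de$gene == "geneB", ]
  expect_equal(gB$direction, "ns")
  gC <- de[de$gene == "geneC", ]
  expect_equal(gC$log2fc, 0)        # blanketed everywhere
  expect_equal(gC$direction, "ns")
  expect_true(all(de$padj >= de$p))
})

test_that("NB test recovers strong simulated fold changes", {
  set.seed(61)
  hits <- sapply(1:25, function(i) {
    s <- simulate_nanostring_counts(n_genes = 40, n_true_de = 4,
                                    log2fc = 2, dispersion = 0.05,
                                    seed = 6100 + i)
    cm <- count_matrix(s$counts, s$probe_class, s$sample_group)
    de <- nb_differential_test(normalize_ncounter(cm)$matrix, "a", "b")
    idx <- match(s$truth$de_genes, de$gene)
    ok_dir <- de$direction[idx] ==
      ifelse(s$truth$de_direction > 0, "up", "down")
    c(called = mean(de$significant[idx]),
      dir = mean(ok_dir[de$significant[idx]]))
  })
  expect_gte(mean(hits["called", ]), 0.95)
  expect_gte(mean(hits["dir", ], na.rm = TRUE), 0.95)
})

test_that("concordance tally matches a hand-built reference", {
  mk_de <- function(genes, dirs, sig) {
    data.frame(gene = genes, mean_a = 10, mean_b = 10,
               log2fc = ifelse(dirs == "up", 1, ifelse(dirs == "down", -1, 0)),
               p = ifelse(sig, 0.01, 0.5), padj = ifelse(sig, 0.05, 0.7),
               significant = sig, direction = ifelse(sig, dirs, "ns"))
  }
  genes <- paste0("g", 1:6)
  ref <- data.frame(gene = genes,
                    direction = c(rep("low_in_SZPNT", 3),
                                  rep("high_in_SZPNT", 3)))
  # g1 down at day1; g2 down at day6 only; g3 never; g4 up at day1;
  # g5 wrong direction; g6 not significant
  de1 <- mk_de(genes, c("down", "up", "up", "up", "down", "up"),
               c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  de6 <- mk_de(genes, c("down", "down", "up", "up", "down", "up"),
               c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  r <- concordance_analysis(de1, de6, ref)
  expect_equal(r$n_down_concordant, 2)
  expect_equal(r$n_up_concordant, 1)
  expect_equal(unname(r$table["low_in_SZPNT", ]), c(2, 1))
  expect_equal(unname(r$table["high_in_SZPNT", ]), c(1, 2))
  expect_equal(r$fisher_p, fisher_exact_2x2(r$table))

  # fully concordant reference saturates both rows: no association
  de_conc <- mk_de(genes, c(rep("down", 3), rep("up", 3)), rep(TRUE, 6))
  r_sat <- concordance_analysis(de_conc, de_conc, ref)
  expect_equal(unname(r_sat$table[, "concordant"]), c(3, 3))
  expect_equal(r_sat$fisher_p, 1)

  # unmatched genes are excluded with a warning
  ref2 <- rbind(ref, data.frame(gene = "g99", direction = "low_in_SZPNT"))
  expect_warning(r2 <- concordance_analysis(de1, de6, ref2), "g99")
  expect_equal(r2$n_low_total, 3)
})

test_that("volcano table derives its columns without recomputation", {
  de <- data.frame(gene = c("g1", "g2"), mean_a = c(10, 1), mean_b = c(40, 1),
                   log2fc = c(2, 0), p = c(0.01, 0.8), padj = c(0.02, 0.9),
                   significant = c(TRUE, FALSE), direction = c("up", "ns"))
  v <- volcano_table(de)
  expect_equal(v$neg_log10_p[1], 2)
  expect_equal(v$class, c("up", "ns"))
  expect_equal(v$mean_counts, c(25, 1))
})
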