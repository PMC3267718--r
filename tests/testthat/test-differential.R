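# ---- splicing index ---------------------------------------------------------

test_that("splicing index is the exon-minus-gene log2 difference", {
  ann <- toy_annotation(clusters = 1L, probesets = 2L)
  gene <- matrix(8, 1, 3, dimnames = list("TC01", paste0("S", 1:3)))
  exon <- matrix(c(8, 10, 8, 10, 8, 10), 2, 3,
                 dimnames = list(ann$probeset_id, paste0("S", 1:3)))
  si <- splicing_index(exon, gene, ann)
  expect_equal(unname(si[1L, ]), rep(0, 3))   # exon equals its gene
  expect_equal(unname(si[2L, ]), rep(2, 3))   # exon at 4x its gene

  # joint shifts of exon and gene rows cancel
  si2 <- splicing_index(exon + 1, gene + 1, ann)
  expect_equal(si2, si, ignore_attr = TRUE)

  # orphan exon is an error listing the id
  gene_wrong <- matrix(8, 1, 3, dimnames = list("TC99", paste0("S", 1:3)))
  expect_error(splicing_index(exon, gene_wrong, ann), "TC01_PS01")
})

# ---- fold change ------------------------------------------------------------

test_that("fold changes follow the HLHS-over-control orientation convention", {
  design <- toy_design(c(HLHS_RV = 3L, Control_RV = 3L))
  m <- rbind(equal = rep(5, 6), up = c(6, 6, 6, 5, 5, 5),
             down = c(5 - 1.737, 5 - 1.737, 5 - 1.737, 5, 5, 5))
  colnames(m) <- design$sample_id
  fc <- fold_change(m, design, "HLHS_RV", "Control_RV")
  expect_equal(fc[["equal"]], 1)
  expect_equal(fc[["up"]], 2)
  expect_equal(fc[["down"]], 2^-1.737, tolerance = 1e-12)
  expect_equal(round(fc[["down"]], 1), 0.3)  # down-regulation printed as a fraction
  expect_error(fold_change(m, design, "HLHS_RV", "nope"), "nope")
})

# ---- ANOVA ------------------------------------------------------------------

test_that("one-way F collapses to zero when group means are identical", {
  design <- toy_design(c(A = 3L, B = 3L, C = 3L))
  block <- c(1, 2, 3)
  m <- matrix(rep(block, 3), 1, 9, dimnames = list("f", design$sample_id))
  an <- row_oneway_anova(m, design)
  expect_equal(an$F, 0)
  expect_equal(an$p, 1)
})

test_that("F equals t-squared for two groups", {
  design <- toy_design(c(A = 4L, B = 5L))
  set.seed(3)
  m <- matrix(rnorm(9 * 50), 50, 9,
              dimnames = list(paste0("f", 1:50), design$sample_id))
  an <- row_oneway_anova(m, design)
  tt <- two_group_test(m, design, "A", "B", variant = "pooled")
  expect_equal(an$F, tt$t^2, tolerance = 1e-10)
  expect_equal(an$p, tt$p, tolerance = 1e-10)
})

test_that("ANOVA p-values are uniform under the null", {
  design <- toy_design()
  set.seed(4)
  m <- matrix(rnorm(16 * 10000), 10000, 16,
              dimnames = list(paste0("f", 1:10000), design$sample_id))
  an <- row_oneway_anova(m, design)
  ks <- suppressWarnings(stats::ks.test(an$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ANOVA matches stats::aov on a small example and flags degeneracy", {
  design <- toy_design(c(A = 3L, B = 3L, C = 4L))
  set.seed(5)
  x <- rnorm(10)
  m <- matrix(x, 1, 10, dimnames = list("f", design$sample_id))
  an <- row_oneway_anova(m, design)
  fit <- summary(stats::aov(x ~ factor(design$group)))[[1L]]
  expect_equal(an$F, fit$`F value`[1L], tolerance = 1e-10)
  expect_equal(an$p, fit$`Pr(>F)`[1L], tolerance = 1e-10)

  m2 <- rbind(sep = rep(c(0, 1, 2), c(3, 3, 4)), const = rep(1, 10))
  colnames(m2) <- design$sample_id
  an2 <- row_oneway_anova(m2, design)
  expect_true(all(an2$degenerate))
  expect_equal(an2["sep", "p"], 0)       # zero residual, unequal means
  expect_true(is.na(an2["const", "p"]))  # constant feature: undefined
})

# ---- t-tests ----------------------------------------------------------------

test_that("pooled t matches the textbook formula and t.test", {
  design <- toy_design(c(A = 3L, B = 3L))
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  m <- matrix(c(a, b), 1, 6, dimnames = list("f", design$sample_id))
  got <- two_group_test(m, design, "A", "B", variant = "pooled")
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1/3 + 1/3))
  expect_equal(got$t, t_hand, tolerance = 1e-10)
  expect_equal(got$p, 2 * pt(abs(t_hand), 4, lower.tail = FALSE), tolerance = 1e-10)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)

  # identical groups
  m0 <- matrix(rep(c(1, 2, 3), 2), 1, 6, dimnames = list("f", design$sample_id))
  got0 <- two_group_test(m0, design, "A", "B")
  expect_equal(got0$t, 0)
  expect_equal(got0$p, 1)
})

test_that("welch variant matches stats::t.test", {
  design <- toy_design(c(A = 4L, B = 6L))
  set.seed(6)
  m <- matrix(rnorm(10 * 20, sd = rep(c(1, 3), each = 5)), 20, 10,
              dimnames = list(paste0("f", 1:20), design$sample_id))
  got <- two_group_test(m, design, "A", "B", variant = "welch")
  for (i in c(1L, 7L, 20L)) {
    ref <- stats::t.test(m[i, 1:4], m[i, 5:10])
    expect_equal(got$t[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p[i], ref$p.value, tolerance = 1e-10)
    expect_equal(got$df[i], unname(ref$parameter), tolerance = 1e-10)
  }
})

test_that("moderated t collapses to the common-variance statistic as d0 -> Inf", {
  design <- toy_design(c(A = 4L, B = 4L))
  set.seed(7)
  base <- matrix(rnorm(8 * 200), 200, 8)
  # equal true variances and tiny between-feature spread force d0 = Inf
  m <- base
  dimnames(m) <- list(paste0("f", 1:200), design$sample_id)
  # construct variances so across-feature CV^2 * d <= 2 (moment match -> Inf)
  got <- two_group_test(m, design, "A", "B", variant = "moderated")
  d <- 6
  s2 <- apply(m, 1L, function(x) ((3) * var(x[1:4]) + 3 * var(x[5:8])) / d)
  cv2 <- var(s2) / mean(s2)^2
  if (cv2 * d <= 2) {
    s0 <- sqrt(mean(s2))
    expect_equal(got$t,
                 unname((rowMeans(m[, 1:4]) - rowMeans(m[, 5:8])) /
                          (s0 * sqrt(1/4 + 1/4))),
                 tolerance = 1e-10)
  } else {
    # moderated |t| sits between the raw pooled |t| scaled by extreme variances
    tt <- two_group_test(m, design, "A", "B", variant = "pooled")
    expect_true(all(is.finite(got$t)))
    expect_gt(cor(got$t, tt$t), 0.98)
  }
})

test_that("moderated t shrinks outlying variances toward the prior", {
  design <- toy_design(c(A = 4L, B = 4L))
  set.seed(8)
  m <- matrix(rnorm(8 * 500), 500, 8,
              dimnames = list(paste0("f", 1:500), design$sample_id))
  m[1L, ] <- m[1L, ] * 0.01  # near-zero variance feature
  m[1L, 1:4] <- m[1L, 1:4] + 0.05
  pooled <- two_group_test(m, design, "A", "B", variant = "pooled")
  mod <- two_group_test(m, design, "A", "B", variant = "moderated")
  # the tiny-variance feature's inflated pooled t is pulled in
  expect_lt(abs(mod$t[1L]), abs(pooled$t[1L]))
})

# ---- BH FDR -----------------------------------------------------------------

test_that("BH adjustment reproduces hand-traced step-up examples", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_fdr(c(0.5, 0.005)), c(0.5, 0.01))  # order preserved
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
})

test_that("BH handles missing values by excluding them from m", {
  p <- c(0.01, NA, 0.04, NA, 0.03, 0.02)
  got <- bh_fdr(p)
  expect_true(all(is.na(got[c(2L, 4L)])))
  expect_equal(got[!is.na(p)], bh_fdr(p[!is.na(p)]))
})

test_that("BH equals p.adjust and the threshold-scan oracle on random inputs", {
  set.seed(9)
  for (i in 1:20) {
    m <- sample(1:10, 1L)
    p <- round(runif(m), 3)
    got <- bh_fdr(p)
    expect_equal(got, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_equal(got, bh_oracle(p), tolerance = 1e-12)
  }
  # monotone over the ascending sort
  p <- sort(runif(50))
  expect_true(all(diff(bh_fdr(p)) >= 0))
})

# ---- selection --------------------------------------------------------------

fake_table <- function(fc, anova_fdr, pair_fdr, level = "gene") {
  out <- data.frame(feature_id = paste0("f", seq_along(fc)), level = level,
                    anova_F = 1, anova_p = anova_fdr, anova_fdr = anova_fdr,
                    fc_A_vs_B = fc, t_A_vs_B = 1, p_A_vs_B = pair_fdr,
                    fdr_A_vs_B = pair_fdr, stringsAsFactors = FALSE)
  class(out) <- c("differential_table", "data.frame")
  out
}

test_that("compound selection applies the fold threshold symmetrically", {
  tab <- fake_table(fc = c(1.6, 1.4, 0.6, 2.5),
                    anova_fdr = c(0.04, 0.04, 0.04, 0.04),
                    pair_fdr = c(0.04, 0.04, 0.04, 0.2))
  crit <- selection_criteria()
  got <- select_features(tab, crit, "A_vs_B")
  expect_setequal(got, c("f1", "f3"))  # 0.6-fold (1/0.6 > 1.5) passes; 1.4 fails
})

test_that("relaxing any threshold never shrinks the selected set", {
  set.seed(10)
  tab <- fake_table(fc = exp(rnorm(200, 0, 0.6)),
                    anova_fdr = runif(200), pair_fdr = runif(200))
  base <- select_features(tab, selection_criteria(), "A_vs_B")
  for (crit in list(selection_criteria(anova_fdr_max = 0.2),
                    selection_criteria(pair_fdr_max = 0.2),
                    selection_criteria(min_fold = 1.2))) {
    expect_true(all(base %in% select_features(tab, crit, "A_vs_B")))
  }
})

test_that("clustering gate uses the 2-fold gene and 5-fold splicing thresholds", {
  tab_g <- fake_table(fc = c(1.8, 2.5), anova_fdr = c(0.01, 0.01),
                      pair_fdr = c(0.01, 0.01), level = "gene")
  expect_equal(select_for_clustering(tab_g, selection_criteria(), "A_vs_B"), "f2")
  tab_e <- fake_table(fc = c(4.5, 6), anova_fdr = c(0.01, 0.01),
                      pair_fdr = c(0.01, 0.01), level = "exon")
  expect_equal(select_for_clustering(tab_e, selection_criteria(), "A_vs_B"), "f2")
})

# ---- qPCR -------------------------------------------------------------------

test_that("delta-delta-Ct folds match a spreadsheet-style oracle", {
  design <- toy_design(c(HLHS_RV = 2L, Control_RV = 2L))
  ct <- rbind(r18s = c(10, 10.5, 10.2, 10.1),
              flat = c(20, 20.5, 20.2, 20.1),   # tracks the reference: fold 1
              up1  = c(19, 19.5, 20.2, 20.1),   # one cycle earlier in HLHS
              g3   = c(25, 24, 26, 27))
  colnames(ct) <- design$sample_id
  got <- qpcr_fold_change(ct, "r18s", design, "HLHS_RV", "Control_RV")
  dct <- sweep(ct, 2, ct["r18s", ])
  oracle <- 2 ^ (rowMeans(dct[, 3:4]) - rowMeans(dct[, 1:2]))
  expect_equal(got, oracle[names(got)], tolerance = 1e-12)
  expect_equal(got[["flat"]], 1)
  expect_equal(got[["up1"]], 2)
  expect_false("r18s" %in% names(got))
  expect_error(qpcr_fold_change(ct, "gapdh", design, "HLHS_RV", "Control_RV"),
               "gapdh")
})
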