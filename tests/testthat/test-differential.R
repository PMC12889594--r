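test_that("G test matches closed forms and the likelihood-ratio oracle", {
  r <- g_test(5, 10, 5, 10)
  expect_equal(r$G, 0)
  expect_equal(r$p, 1)
  r <- g_test(10, 10, 0, 10)
  expect_equal(r$G, 40 * log(2), tolerance = 1e-12)
  expect_equal(r$p, pchisq(40 * log(2), 1, lower.tail = FALSE),
               tolerance = 1e-12)
  r <- g_test(8, 10, 3, 10)
  expect_equal(r$G, 5.300218, tolerance = 1e-6)     # 2 * sum O ln(O/E)
  expect_equal(r$p, 0.02132276, tolerance = 1e-6)
  # degenerate margins: all detected or all missing in both groups
  expect_equal(g_test(10, 10, 7, 7)$p, 1)
  expect_equal(g_test(0, 5, 0, 9)$G, 0)

  set.seed(10)
  for (i in 1:1000) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(g_test(k1, n1, k2, n2)$G, oracle_lr_2x2(k1, n1, k2, n2),
                 tolerance = 1e-10)
  }
})

test_that("equalizing imputation follows the gate and touches only the deficient group", {
  vals1 <- c(a1 = 20, a2 = NA, a3 = 21, a4 = NA)
  vals2 <- c(b1 = 19, b2 = 20, b3 = 21, b4 = 22)
  fl1 <- c(a1 = 15, a2 = 14, a3 = 15, a4 = 13)
  fl2 <- c(b1 = 15, b2 = 15, b3 = 15, b4 = 15)
  # gate closed: untouched
  r <- equalizing_impute(vals1, vals2, fl1, fl2, g_p = 0.5)
  expect_identical(r$values1, vals1)
  expect_identical(r$imputed_count, 0L)
  # gate open: deficit of 2 filled with the sample floors, ascending id order
  r <- equalizing_impute(vals1, vals2, fl1, fl2, g_p = 0.01)
  expect_identical(r$imputed_count, 2L)
  expect_equal(r$values1[["a2"]], 14)
  expect_equal(r$values1[["a4"]], 13)
  expect_identical(r$values2, vals2)
  # equal detections: no change even when the gate is open
  v1 <- c(a1 = 20, a2 = NA); v2 <- c(b1 = 19, b2 = NA)
  r <- equalizing_impute(v1, v2, fl1[1:2], fl2[1:2], g_p = 0.001)
  expect_identical(r$imputed_count, 0L)
  # 10/10 vs 4/10 -> exactly 6 imputed, detections equalized
  v1 <- setNames(rnorm(10, 20), sprintf("a%02d", 1:10))
  v2 <- setNames(c(rnorm(4, 20), rep(NA, 6)), sprintf("b%02d", 1:10))
  r <- equalizing_impute(v1, v2, setNames(rep(15, 10), names(v1)),
                         setNames(rep(15, 10), names(v2)), g_p = 0.001)
  expect_identical(r$imputed_count, 6L)
  expect_identical(sum(!is.na(r$values2)), 10L)
  expect_identical(r$values1, v1)
})

test_that("imputation never widens the detection gap (random cases)", {
  set.seed(20)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    v1 <- setNames(ifelse(runif(n) < 0.5, rnorm(n, 20), NA),
                   sprintf("a%02d", seq_len(n)))
    v2 <- setNames(ifelse(runif(n) < 0.5, rnorm(n, 20), NA),
                   sprintf("b%02d", seq_len(n)))
    fl <- setNames(rep(15, n), names(v1))
    fl2 <- setNames(rep(15, n), names(v2))
    gp <- runif(1, 0, 0.1)
    r <- equalizing_impute(v1, v2, fl, fl2, g_p = gp)
    gap0 <- abs(sum(!is.na(v1)) - sum(!is.na(v2)))
    gap1 <- abs(sum(!is.na(r$values1)) - sum(!is.na(r$values2)))
    expect_lte(gap1, gap0)
    # the better-detected group is never modified
    if (sum(!is.na(v1)) >= sum(!is.na(v2))) expect_identical(r$values1, v1)
    if (sum(!is.na(v2)) >= sum(!is.na(v1))) expect_identical(r$values2, v2)
    # with enough missing cells the gap closes completely
    if (gp < 0.05) {
      deficient_missing <- if (sum(!is.na(v1)) < sum(!is.na(v2)))
        sum(is.na(v1)) else sum(is.na(v2))
      if (deficient_missing >= gap0) expect_identical(gap1, 0L)
    }
  }
})

test_that("moderated t reduces to the classical paired t at d_0 = 0", {
  res <- moderated_paired_ttest(matrix(c(1, 2, 3), 1, 3), d_0 = 0, s2_0 = 1)
  expect_equal(res$t_mod, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$df_total, 2)
  ct <- t.test(c(1, 2, 3))
  expect_equal(res$p, ct$p.value, tolerance = 1e-10)
})

test_that("moderation formula matches plug-in priors and handles null signal", {
  res <- moderated_paired_ttest(matrix(c(1, 2, 3), 1, 3), d_0 = 3, s2_0 = 1)
  # posterior variance (3*1 + 2*1)/5 = 1 -> same t, more df
  expect_equal(res$t_mod, 3.464, tolerance = 1e-3)
  expect_equal(res$df_total, 5)
  expect_equal(res$p, 2 * pt(3.464102, 5, lower.tail = FALSE),
               tolerance = 1e-6)
  res0 <- moderated_paired_ttest(matrix(0, 1, 4), d_0 = 0, s2_0 = 0)
  expect_equal(res0$t_mod, 0)
  expect_equal(res0$p, 1)
})

test_that("variance prior estimation agrees with limma's empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(30)
  s2 <- 0.8 * rchisq(500, df = 6) / 6
  fit <- fit_variance_prior(s2, df = 6)
  sq <- limma::squeezeVar(s2, df = 6)
  expect_equal(fit$s2_0, sq$var.prior, tolerance = 1e-4)
  expect_equal(fit$d_0, sq$df.prior, tolerance = 1e-3)
  # posterior variances agree too
  post <- (fit$d_0 * fit$s2_0 + 6 * s2) / (fit$d_0 + 6)
  expect_equal(post, sq$var.post, tolerance = 1e-4)
})

test_that("posterior variance tends to the prior as d_0 grows", {
  set.seed(31)
  diffs <- matrix(rnorm(60 * 3), 60, 3)
  res <- moderated_paired_ttest(diffs, d_0 = 1e6, s2_0 = 1)
  s2_post <- (1e6 * 1 + res$d_g * res$s2_g) / (1e6 + res$d_g)
  expect_true(all(abs(s2_post - 1) < 1e-4))
})

test_that("BH q-values agree with the brute-force step-up", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(40)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  # NA handling: excluded from m, returned as NA
  q <- bh_fdr(c(0.01, NA, 0.02))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], oracle_bh(c(0.01, 0.02)))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("log2FC z-scores standardize with sample sd and reject degenerate input", {
  expect_equal(log2fc_zscores(c(-1, 0, 1)), c(-1, 0, 1))
  expect_equal(log2fc_zscores(c(0, 0, 0, 5)), c(-0.5, -0.5, -0.5, 1.5))
  expect_error(log2fc_zscores(rep(2, 5)), "degenerate")
  expect_error(log2fc_zscores(1), "two finite")
})

test_that("DAP calls respect species-specific z thresholds", {
  rec <- data.frame(protein_id = c("A", "B"), log2fc = c(1, 1),
                    z = c(3.0, 2.2), p = c(1e-4, 1e-4),
                    q = c(0.01, 0.01), tested = TRUE)
  mouse <- call_daps(rec, z_threshold = species_z_threshold("5xFAD"))
  expect_identical(mouse$is_dap, c(TRUE, FALSE))
  human <- call_daps(rec, z_threshold = species_z_threshold("human"))
  expect_identical(human$is_dap, c(TRUE, TRUE))
  # failing FDR blocks the call regardless of z
  rec$q <- c(0.2, 0.2)
  expect_false(any(call_daps(rec, z_threshold = 2)$is_dap))
})

test_that("the differential stage is invariant to protein row order", {
  cfg <- cohort_config(n_proteins = 150, n_pairs_per_age = 8, seed = 13)
  co <- generate_cohort(cfg)
  m <- co$matrix
  rec1 <- dap_analysis(subset_stratum(m, "5xFAD", 3))
  perm <- sample(nrow(m$values))
  m2 <- IntensityMatrix(m$values[perm, ], m$metadata)
  rec2 <- dap_analysis(subset_stratum(m2, "5xFAD", 3))
  rec2 <- rec2[match(rec1$protein_id, rec2$protein_id), ]
  expect_equal(rec1$q, rec2$q, tolerance = 1e-12)
  expect_identical(rec1$is_dap, rec2$is_dap)
})

test_that("tracer correlation screen matches the Pearson oracle and sign conventions", {
  set.seed(50)
  cfg <- cohort_config(n_proteins = 60, n_pairs_per_age = 8,
                       n_blocks = 2, block_size = 10, frac_contaminant = 0,
                       missing_midpoint = -Inf, missing_slope = 0, seed = 14)
  co <- generate_cohort(cfg)
  m <- co$matrix
  # plant a perfect correlate and a perfect anticorrelate of the tracer
  pl <- m$metadata$sample_id[m$metadata$region == "plaque"]
  m$values["P0001", ] <- m$values["ABETA_TRACER", ] + 0.5
  m$values["P0002", ] <- -m$values["ABETA_TRACER", ] + 40
  scr <- tracer_correlation_screen(m, "ABETA_TRACER")
  expect_identical(scr$protein_id[1], "P0001")
  expect_equal(scr$r[scr$protein_id == "P0001"], 1, tolerance = 1e-12)
  expect_equal(scr$r[scr$protein_id == "P0002"], -1, tolerance = 1e-12)
  expect_false(scr$passes_threshold[scr$protein_id == "P0002"])
  tr <- m$values["ABETA_TRACER", pl]
  for (id in sample(setdiff(rownames(m$values), "ABETA_TRACER"), 10)) {
    expect_equal(scr$r[scr$protein_id == id],
                 oracle_pearson(m$values[id, pl], tr), tolerance = 1e-12)
  }
})
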