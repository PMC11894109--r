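test_that("moderated t with prior df forced to 0 equals the closed-form pooled t", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
              dimnames = list("p1", sprintf("s%d", 1:6)))
  lab <- factor(c("inactive", "inactive", "inactive", "active", "active", "active"),
                levels = c("inactive", "active"))
  names(lab) <- colnames(x)
  cl <- methods::new("ActivityClasses", labels = lab, tag = "Mayo_Prob_1")
  de <- fitModeratedT(x, cl, prior_df = 0)
  # pooled s2 = 1, t = 3 / sqrt(1 * (1/3 + 1/3)) = 3.674, df = 4
  expect_equal(de$t_moderated, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(de$p_unadjusted, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-12)
  expect_equal(de$log2_fold_change, 3, tolerance = 1e-12)
})

test_that("identical per-probe sample variances collapse moderation to the ordinary t", {
  # same within-group residual pattern on every probe => identical s_g^2
  base <- handMatrix(n_probes = 1, n_per_class = 6, seed = 8)
  resid <- sweep(base$x, 1, rowMeans(base$x))
  x <- matrix(rep(resid, each = 40), nrow = 40) +
    matrix(rnorm(40), 40, ncol(resid))  # distinct probe means, shared residuals
  dimnames(x) <- list(sprintf("P%02d", 1:40), colnames(base$x))
  de <- fitModeratedT(x, base$classes)          # estimated prior
  de0 <- fitModeratedT(x, base$classes, prior_df = 0)  # ordinary t
  nz <- de0$t_moderated != 0
  expect_lt(max(abs(de$t_moderated[nz] - de0$t_moderated[nz]) /
                  abs(de0$t_moderated[nz])), 1e-6)
})

test_that("moderated t and variance prior match the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(3)
  x <- matrix(rnorm(300 * 24, 8, 1), 300, 24) *
    matrix(exp(rnorm(300, 0, 0.3)), 300, 24)
  dimnames(x) <- list(sprintf("P%03d", 1:300), sprintf("S%02d", 1:24))
  lab <- factor(rep(c("inactive", "active"), each = 12),
                levels = c("inactive", "active"))
  names(lab) <- colnames(x)
  cl <- methods::new("ActivityClasses", labels = lab, tag = "Mayo_Prob_1")
  de <- fitModeratedT(x, cl)
  fit <- limma::eBayes(limma::lmFit(x, cbind(1, as.integer(lab == "active"))))
  mod <- attr(de, "moderation")
  expect_equal(mod$prior_df, fit$df.prior, tolerance = 1e-8)
  expect_equal(mod$prior_var, fit$s2.prior, tolerance = 1e-8)
  expect_equal(de$t_moderated, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(de$p_unadjusted, unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("moderation shrinks the null t spread relative to the ordinary t", {
  hm <- handMatrix(n_probes = 800, n_per_class = 5, seed = 21)
  de <- fitModeratedT(hm$x, hm$classes)
  de0 <- fitModeratedT(hm$x, hm$classes, prior_df = 0)
  expect_gt(attr(de, "moderation")$prior_df, 0)
  expect_lt(var(de$t_moderated), var(de0$t_moderated))
})

test_that("DE table invariants hold and degenerate probes are flagged", {
  co <- plantedCohort()
  cl <- defineActivityClasses(co)
  de <- fitModeratedT(co, cl)
  expect_true(all(de$p_fdr >= de$p_unadjusted - 1e-15))
  expect_equal(de$log2_fold_change,
               log2(de$mean_active) - log2(de$mean_inactive), tolerance = 1e-9)
  # linear group means are 2^(mean log2) exactly
  x <- exprsMatrix(co)
  act <- includedSamples(cl)[classLabels(cl) == "active"]
  expect_equal(de$mean_active, unname(2^rowMeans(x[, act])), tolerance = 1e-12)

  # constant probe: flagged, t = 0, p = 1
  hm <- handMatrix(n_probes = 4, n_per_class = 4, seed = 2)
  hm$x[1, ] <- 5
  de2 <- fitModeratedT(hm$x, hm$classes)
  expect_true(de2$zero_variance[1])
  expect_identical(de2$t_moderated[1], 0)
  expect_identical(de2$p_unadjusted[1], 1)
})

test_that("BH adjustment matches the hand-run example and the p.adjust oracle", {
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4), tolerance = 1e-15)
  expect_identical(benjaminiHochberg(0.2), 0.2)
  set.seed(11)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_identical(benjaminiHochberg(p), p.adjust(p, "BH"))
  }
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(benjaminiHochberg(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("transcript ranking obeys direction, tie-breaks, and gene collapse", {
  de <- data.frame(
    probe_id = c("pA1", "pA2", "pB", "pC", "pD"),
    gene_symbol = c("GA", "GA", "GB", "GC", "GD"),
    mean_active = 2, mean_inactive = 1, mean_control = 1,
    log2_fold_change = c(2, 1.2, 1.5, 2.0, -0.8),
    t_moderated = 5,
    p_unadjusted = c(1e-8, 1e-5, 1e-3, 1e-3, 1e-6),
    p_fdr = c(1e-6, 1e-4, 1e-2, 1e-2, 1e-5),
    zero_variance = FALSE, stringsAsFactors = FALSE
  )
  up <- rankTranscripts(de, "increased", k = 10)
  expect_identical(up$probe_id, c("pA1", "pA2", "pC", "pB"))  # tie: |FC| 2.0 > 1.5
  up_c <- rankTranscripts(de, "increased", k = 10, collapse_to_genes = TRUE)
  expect_identical(up_c$probe_id, c("pA1", "pC", "pB"))       # GA keeps best probe
  down <- rankTranscripts(de, "decreased", k = 10)
  expect_identical(down$probe_id, "pD")
  expect_error(rankTranscripts(de, "increased", k = 0), "> 0")
})

test_that("top-30 increased list is dominated by planted truth", {
  co <- plantedCohort()
  de <- fitModeratedT(co, defineActivityClasses(co, include_ibdu = TRUE))
  tr <- cohortTruth(co)
  top <- rankTranscripts(de, "increased", k = 30)
  expect_gte(mean(top$probe_id %in% tr$signal_probesets), 0.9)
})

test_that("volcano table computes -log10 p, flags, and the FDR line", {
  co <- plantedCohort()
  de <- fitModeratedT(co, defineActivityClasses(co))
  v <- volcanoTable(de, co)
  i <- which(abs(de$p_unadjusted - 0.01) == min(abs(de$p_unadjusted - 0.01)))[1]
  expect_equal(v$neg_log10_p[i], -log10(de$p_unadjusted[i]))
  tr <- cohortTruth(co)
  expect_setequal(v$flag[match(tr$s100_probesets, v$probe_id)], "calprotectin")
  # FDR line: the marked probe has the largest p among FDR < 0.05
  expect_identical(sum(v$fdr_line), 1L)
  marked <- which(v$fdr_line)
  expect_lt(de$p_fdr[marked], 0.05)
  expect_equal(de$p_unadjusted[marked], max(de$p_unadjusted[de$p_fdr < 0.05]))
  # no FDR hits -> marker absent
  de_null <- de
  de_null$p_fdr <- pmax(de_null$p_fdr, 0.2)
  expect_identical(sum(volcanoTable(de_null)$fdr_line), 0L)
})
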