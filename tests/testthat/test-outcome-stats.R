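test_that("spearman correlation handles monotone, tied, and constant inputs", {
  x <- c(3, 7, 9, 15, 20)
  expect_equal(spearmanTest(x, exp(x))$rho, 1)
  expect_equal(spearmanTest(x, -x^3)$rho, -1)
  expect_identical(spearmanTest(x, exp(x))$p, 0)
  # tied pair: oracle is Pearson on midranks with the t-approximation p
  x2 <- c(1, 2, 3, 4); y2 <- c(1, 1, 3, 4)
  res <- spearmanTest(x2, y2)
  rho_oracle <- cor(rank(x2), rank(y2))
  expect_equal(res$rho, rho_oracle, tolerance = 1e-15)
  t_or <- rho_oracle * sqrt(2 / (1 - rho_oracle^2))
  expect_equal(res$p, 2 * pt(-abs(t_or), 2), tolerance = 1e-12)
  # constant vector: explicit undefined marker, never 0
  cst <- spearmanTest(rep(2, 6), 1:6)
  expect_true(cst$undefined)
  expect_identical(cst$rho, NA_real_)
  # incomplete pairs dropped, n reported; too few complete pairs refused
  expect_identical(spearmanTest(c(1, 2, NA, 4, 5, 6), c(2, 1, 3, 4, 6, NA))$n, 4L)
  expect_error(spearmanTest(c(1, 2, NA, 4), c(1, NA, 3, 4)), ">= 4")
  # self-correlation of any non-constant x is 1
  set.seed(1)
  for (i in 1:20) {
    z <- rnorm(sample(4:30, 1))
    expect_equal(spearmanTest(z, z)$rho, 1)
  }
})

test_that("Welch test matches the closed form and is antisymmetric", {
  res <- welchTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4, tolerance = 1e-12)
  sw <- welchTest(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sw$t, -res$t, tolerance = 1e-15)
  expect_equal(sw$p, res$p, tolerance = 1e-15)
  same <- welchTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welchTest(c(2, 2, 2), c(5, 5)), "degenerate")
})

test_that("Mann-Whitney AUC: separation, ties, transforms, null mean", {
  expect_identical(aucMannWhitney(c(1, 2, 3, 10, 11, 12),
                                  c(F, F, F, T, T, T)), 1)
  expect_identical(aucMannWhitney(rep(5, 8), rep(c(TRUE, FALSE), 4)), 0.5)
  set.seed(2)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5)
  expect_equal(aucMannWhitney(qlogis(plogis(s)), y), aucMannWhitney(s, y),
               tolerance = 1e-12)
  expect_equal(aucMannWhitney(exp(s), y), aucMannWhitney(s, y), tolerance = 1e-12)
  expect_error(aucMannWhitney(s, rep(TRUE, 40)), "both classes")
  # null: mean AUC over resamples is 0.5
  set.seed(3)
  null_auc <- replicate(10000, {
    aucMannWhitney(rnorm(20), rep(c(TRUE, FALSE), each = 10))
  })
  expect_lt(abs(mean(null_auc) - 0.5), 0.02)
})

test_that("predictor table wires scores, covariates, and the outcome split", {
  co <- plantedCohort()
  cl1 <- defineActivityClasses(co, FALSE)
  cv1 <- crossValidate(co, cl1, k = 5, seed = 1,
                       roster = defaultLearnerRoster()["lda"])
  mc <- mcalproScore(co)
  pred <- buildPredictorTable(co, cv1, NULL, mc)
  s <- sampleInfo(co)
  expect_setequal(pred$sample_id, rownames(s)[s$diagnosis != "control"])
  # IBDU samples have no Mayo_Prob_1 score
  ibdu <- rownames(s)[s$diagnosis == "IBDU"]
  expect_true(all(is.na(pred$mayo_prob_1[pred$sample_id %in% ibdu])))
  # outcome is the > 1 dichotomy of the status code
  st <- s[pred$sample_id, "status_code"]
  expect_identical(pred$poor_outcome, ifelse(is.na(st), NA_integer_,
                                             as.integer(st > 1)))
})

test_that("univariate screen is calibrated on null predictors and powered on signal", {
  set.seed(8)
  # null: rejection rate ~ alpha, AUC ~ 0.5
  pvals <- replicate(300, {
    d <- data.frame(poor_outcome = rbinom(200, 1, 0.4), x = rnorm(200))
    singlePredictorScreen(d, columns = "x")$p
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.035)
  # signal: predictor = outcome + small noise
  d <- data.frame(poor_outcome = rbinom(300, 1, 0.5))
  d$x <- d$poor_outcome + rnorm(300, 0, 0.2)
  res <- singlePredictorScreen(d, columns = "x")
  expect_gte(res$auc, 0.95)
  expect_lt(res$p, 1e-6)
  # constant predictor -> undefined marker
  d$z <- 1
  expect_identical(singlePredictorScreen(d, columns = "z")$flag, "undefined")
  # perfect separation is flagged with a finite fallback p
  d$w <- ifelse(d$poor_outcome == 1, 10, -10) + rnorm(300, 0, 0.01)
  resw <- singlePredictorScreen(d, columns = "w")
  expect_identical(resw$flag, "separation")
  expect_true(is.finite(resw$p) && resw$p < 0.05)
})

test_that("LRT: aliased covariates add nothing; true severity is detected", {
  set.seed(12)
  d <- data.frame(poor_outcome = rbinom(120, 1, 0.4),
                  a = rnorm(120))
  d$a_copy <- d$a
  res <- likelihoodRatioCompare(d, "a", c("a", "a_copy"))
  expect_equal(res$lrt, 0, tolerance = 1e-8)
  expect_identical(res$df, 0L)
  expect_identical(res$p, 1)
  expect_error(likelihoodRatioCompare(d, c("a", "a_copy"), "a"), "nested")

  # power: adding the generator's true severity to clinical covariates
  co <- plantedCohort()
  tr <- cohortTruth(co)
  cl <- defineActivityClasses(co, TRUE)
  pred <- buildPredictorTable(co, NULL, NULL, mcalproScore(co))
  pred$severity <- unname(tr$severity[pred$sample_id])
  hits <- 0L
  for (i in 1:20) {
    # resample follow-up noise by refitting on bootstrap rows
    idx <- sample(which(!is.na(pred$poor_outcome)), replace = TRUE)
    res <- tryCatch(
      likelihoodRatioCompare(pred[idx, ], "partial_mayo",
                             c("partial_mayo", "severity")),
      error = function(e) NULL)
    if (!is.null(res) && res$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 15L)
})

test_that("LRT null calibration at moderate n", {
  set.seed(21)
  rej <- replicate(400, {
    d <- data.frame(poor_outcome = rbinom(140, 1, 0.35),
                    clin = rnorm(140), n1 = rnorm(140), n2 = rnorm(140),
                    n3 = rnorm(140))
    likelihoodRatioCompare(d, "clin", c("clin", "n1", "n2", "n3"))$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})

test_that("permutation importance: dominance, nullity, and column-order symmetry", {
  set.seed(30)
  n <- 80
  d <- data.frame(poor_outcome = rbinom(n, 1, 0.5))
  d$dup <- d$poor_outcome + rnorm(n, 0, 0.05)   # near-copy of the outcome
  d$noise1 <- rnorm(n)
  d$noise2 <- rnorm(n)
  imp <- permutationImportance(d, columns = c("dup", "noise1", "noise2"),
                               n_permutations = 20, num_trees = 200, seed = 4)
  expect_identical(imp$predictor[1], "dup")
  expect_gt(imp$importance[1], 0.2)
  # independent predictors hover near zero importance
  expect_lt(max(abs(imp$importance[imp$predictor != "dup"])), 0.05)
  # permuting the column order of the input changes nothing
  d2 <- d[, c("noise2", "poor_outcome", "dup", "noise1")]
  imp2 <- permutationImportance(d2, columns = c("dup", "noise1", "noise2"),
                                n_permutations = 20, num_trees = 200, seed = 4)
  expect_identical(imp2, imp)
  # too few complete cases refused
  d$noise1[1:70] <- NA
  expect_error(permutationImportance(d, columns = c("dup", "noise1", "noise2")),
               "20 complete cases")
})
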