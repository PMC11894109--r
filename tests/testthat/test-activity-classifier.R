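test_that("fold assignment is stratified, balanced, and seed-deterministic", {
  # 60 active / 80 inactive, k = 10 -> exactly 6 active and 8 inactive per fold
  lab <- factor(rep(c("active", "inactive"), c(60, 80)),
                levels = c("inactive", "active"))
  names(lab) <- sprintf("s%03d", 1:140)
  cl <- methods::new("ActivityClasses", labels = lab, tag = "Mayo_Prob_1")
  f <- assignFolds(cl, k = 10, seed = 4)
  expect_true(all(table(f) == 14))
  expect_true(all(table(f[lab == "active"]) == 6))
  expect_identical(f, assignFolds(cl, k = 10, seed = 4))
  expect_false(identical(f, assignFolds(cl, k = 10, seed = 5)))

  # class smaller than k is refused, naming the class
  lab2 <- factor(rep(c("active", "inactive"), c(5, 40)),
                 levels = c("inactive", "active"))
  names(lab2) <- sprintf("t%02d", 1:45)
  cl2 <- methods::new("ActivityClasses", labels = lab2, tag = "Mayo_Prob_1")
  expect_error(assignFolds(cl2, k = 10), "active")
})

test_that("uneven splits keep fold sizes and class counts within one", {
  lab <- factor(rep(c("active", "inactive"), c(53, 71)),
                levels = c("inactive", "active"))
  names(lab) <- sprintf("s%03d", 1:124)
  cl <- methods::new("ActivityClasses", labels = lab, tag = "Mayo_Prob_1")
  for (seed in 1:5) {
    f <- assignFolds(cl, k = 10, seed = seed)
    expect_lte(diff(range(table(f))), 1)
    expect_lte(diff(range(table(f[lab == "active"]))), 1)
    expect_lte(diff(range(table(f[lab == "inactive"]))), 1)
  }
})

test_that("fold-internal feature selection hits the planted signal and never reads test folds", {
  co <- plantedCohort()
  cl <- defineActivityClasses(co, include_ibdu = TRUE)
  tr <- cohortTruth(co)
  f <- assignFolds(cl, k = 10, seed = 2)
  ids <- names(f)
  for (fold in c(1, 5)) {
    train <- ids[f != fold]
    feats <- selectFoldFeatures(co, cl, train)
    expect_length(feats, 20)
    expect_gte(mean(feats %in% tr$signal_probesets), 0.9)
    # leakage probe: poisoning held-out columns must not change the selection
    x <- exprsMatrix(co)
    x[, ids[f == fold]] <- NaN
    expect_identical(selectFoldFeatures(x, cl, train), feats)
  }
  # restricted to exactly m probes, selection is exhaustive
  x20 <- exprsMatrix(co)[1:20, ]
  expect_setequal(selectFoldFeatures(x20, cl, ids[f != 1], m = 20),
                  rownames(x20))
  expect_error(selectFoldFeatures(x20, cl, ids[f != 1], m = 21), "m must be")
})

test_that("a roster of one learner makes the ensemble equal that learner", {
  hm <- handMatrix(n_probes = 30, n_per_class = 15, seed = 6, delta = 1)
  roster <- defaultLearnerRoster()["lda"]
  cl <- hm$classes
  ids <- names(classLabels(cl))
  panel <- trainLearnerPanel(hm$x, cl, ids, rownames(hm$x)[1:5], roster = roster)
  sc <- scoreWithPanel(panel, hm$x, ids)
  expect_identical(nrow(sc), 1L)
  expect_equal(ensembleMedian(sc), sc[1, ], tolerance = 1e-15)
})

test_that("ensemble median follows the definition and is order-invariant", {
  set.seed(9)
  sc <- matrix(runif(12 * 7), nrow = 12,
               dimnames = list(paste0("L", 1:12), paste0("s", 1:7)))
  med <- ensembleMedian(sc)
  manual <- apply(sc, 2, function(v) mean(sort(v)[6:7]))
  expect_equal(med, manual, tolerance = 1e-15)
  expect_equal(ensembleMedian(sc[sample(12), ]), med, tolerance = 1e-15)
  expect_equal(unname(ensembleMedian(matrix(0.7, 3, 2))), c(0.7, 0.7))
})

test_that("panels tolerate constant features and ace a perfectly separating one", {
  hm <- handMatrix(n_probes = 10, n_per_class = 20, seed = 12)
  x <- hm$x
  x[1, ] <- 3                                   # degenerate constant feature
  x[2, ] <- ifelse(classLabels(hm$classes) == "active", 10, 2)  # noiseless
  ids <- names(classLabels(hm$classes))
  panel <- suppressWarnings(
    trainLearnerPanel(x, hm$classes, ids, rownames(x)[1:4], seed = 3))
  sc <- scoreWithPanel(panel, x, ids)
  expect_true(all(sc >= 0 & sc <= 1))
  y <- classLabels(hm$classes) == "active"
  for (nm in rownames(sc)) {
    expect_gte(aucMannWhitney(sc[nm, ], y), 0.999)
  }
})

test_that("panel scoring validates inputs and is constant on constant samples", {
  hm <- handMatrix(n_probes = 8, n_per_class = 12, seed = 13, delta = 1)
  ids <- names(classLabels(hm$classes))
  panel <- trainLearnerPanel(hm$x, hm$classes, ids, rownames(hm$x)[1:4],
                             roster = defaultLearnerRoster()[c("lda", "ridgeLogistic")])
  expect_error(scoreWithPanel(panel, hm$x[2:8, ], ids), "P001")
  flat <- matrix(5, nrow = 8, ncol = 3,
                 dimnames = list(rownames(hm$x), c("n1", "n2", "n3")))
  sc <- scoreWithPanel(panel, flat, c("n1", "n2", "n3"))
  expect_true(all(abs(sc - sc[, 1]) < 1e-12))
})

test_that("cross-validation scores every sample exactly once, out of fold", {
  co <- plantedCohort()
  cl <- defineActivityClasses(co)
  cv <- crossValidate(co, cl, k = 5, seed = 3,
                      roster = defaultLearnerRoster()[c("lda", "rda", "tree")])
  sc <- cvScores(cv)
  expect_setequal(sc$sample_id, includedSamples(cl))
  expect_identical(anyDuplicated(sc$sample_id), 0L)
  expect_true(all(sc$ensemble >= 0 & sc$ensemble <= 1))
  # each sample's fold matches the assignment that would be drawn
  f <- assignFolds(cl, k = 5, seed = 3)
  expect_identical(sc$fold, unname(f[sc$sample_id]))
})

test_that("leave-one-out on a 20-sample toy runs and scores all samples", {
  hm <- handMatrix(n_probes = 25, n_per_class = 10, seed = 14, delta = 1.5)
  cv <- crossValidate(hm$x, hm$classes, k = 10, seed = 2,
                      roster = defaultLearnerRoster()["lda"], n_features = 5)
  expect_identical(nrow(cvScores(cv)), 20L)
})

test_that("ensemble scores rise with the endoscopic Mayo subscore on planted data", {
  co <- plantedCohort()
  cl <- defineActivityClasses(co, include_ibdu = TRUE)
  cv <- crossValidate(co, cl, k = 10, seed = 5)
  sc <- cvScores(cv)
  mayo <- sampleInfo(co)[sc$sample_id, "endoscopic_mayo"]
  grp <- tapply(sc$ensemble, mayo, mean)
  expect_true(all(diff(grp) > -0.02))  # nondecreasing up to simulation noise
  expect_gt(mean(sc$ensemble[sc$class == "active"]),
            mean(sc$ensemble[sc$class == "inactive"]))
  expect_gt(cvAUC(cv), 0.8)
})

test_that("final refit selects 20 seed-free features and round-trips through disk", {
  co <- plantedCohort()
  cl <- defineActivityClasses(co)
  m1 <- fitFinalClassifier(co, cl, seed = 1,
                           roster = defaultLearnerRoster()[c("lda", "elasticNet")])
  m2 <- fitFinalClassifier(co, cl, seed = 99,
                           roster = defaultLearnerRoster()[c("lda", "elasticNet")])
  expect_length(m1@features, 20)
  expect_identical(m1@features, m2@features)  # selection is deterministic
  pred <- predictClassifier(m1, co)
  path <- tempfile(fileext = ".rds")
  saveClassifierModel(m1, path)
  m3 <- loadClassifierModel(path)
  pred3 <- predictClassifier(m3, co)
  expect_identical(pred3$ensemble, pred$ensemble)
  expect_identical(pred3$learner_scores, pred$learner_scores)
})
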