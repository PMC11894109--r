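#' The default 12-learner panel
#'
#' The ensemble aggregates, by median, the "probability of active disease"
#' from 12 commodity classification algorithms: linear discriminant analysis,
#' regularized (shrunken-covariance) discriminant analysis, mixture
#' discriminant analysis, a quadratic (flexible-boundary) discriminant,
#' gradient-boosted trees, radial- and linear-kernel support vector machines
#' with Platt-calibrated probabilities, random forest, a decision tree,
#' a single-hidden-layer neural network, ridge-penalized logistic regression,
#' and elastic-net logistic regression. Hyperparameters are fixed, sensible
#' defaults (no per-fold tuning); each learner has a more-regularized fallback
#' and is dropped with a warning if both fits fail. The roster is an ordinary
#' list, so alternative rosters can be swapped in wherever a `roster`
#' argument is accepted.
#'
#' Every learner receives the same selected features and emits a score in
#' \[0, 1\] for the active class.
#'
#' @return Named list of learner specifications (`fit`, `predict`,
#'   `fallback`).
#' @export
defaultLearnerRoster <- function() {
  list(
    lda = list(
      fit = function(X, y, seed) MASS::lda(X, grouping = y),
      predict = function(m, X) stats::predict(m, X)$posterior[, "active"],
      fallback = function(X, y, seed) .fitRegDA(X, y, gamma = 0.5)
    ),
    rda = list(
      fit = function(X, y, seed) .fitRegDA(X, y, gamma = 0.3),
      predict = function(m, X) .predictRegDA(m, X),
      fallback = function(X, y, seed) .fitRegDA(X, y, gamma = 0.8)
    ),
    mda = list(
      fit = function(X, y, seed) .mclustDA(X, y, type = "MclustDA"),
      predict = function(m, X) .predictMclustDA(m, X),
      fallback = function(X, y, seed) .mclustDA(X, y, type = "EDDA")
    ),
    fda = list(
      fit = function(X, y, seed) MASS::qda(X, grouping = y),
      predict = function(m, X) stats::predict(m, X)$posterior[, "active"],
      fallback = function(X, y, seed) .fitRegDA(X, y, gamma = 0.5)
    ),
    gbm = list(
      fit = function(X, y, seed) {
        .withSeed(seed, {
          d <- xgboost::xgb.DMatrix(X, label = as.numeric(y == "active"))
          xgboost::xgb.train(
            params = list(objective = "binary:logistic", eta = 0.1,
                          max_depth = 2, subsample = 0.8, nthread = 1),
            data = d, nrounds = 60, verbose = 0)
        })
      },
      predict = function(m, X) stats::predict(m, X),
      fallback = function(X, y, seed) {
        .withSeed(seed, {
          d <- xgboost::xgb.DMatrix(X, label = as.numeric(y == "active"))
          xgboost::xgb.train(
            params = list(objective = "binary:logistic", eta = 0.3,
                          max_depth = 1, nthread = 1),
            data = d, nrounds = 20, verbose = 0)
        })
      }
    ),
    svmRadial = list(
      fit = function(X, y, seed)
        .withSeed(seed, e1071::svm(X, y, kernel = "radial", cost = 1,
                                   probability = TRUE)),
      predict = function(m, X)
        attr(stats::predict(m, X, probability = TRUE), "probabilities")[, "active"],
      fallback = function(X, y, seed)
        .withSeed(seed, e1071::svm(X, y, kernel = "radial", cost = 0.1,
                                   probability = TRUE))
    ),
    svmLinear = list(
      fit = function(X, y, seed)
        .withSeed(seed, e1071::svm(X, y, kernel = "linear", cost = 1,
                                   probability = TRUE)),
      predict = function(m, X)
        attr(stats::predict(m, X, probability = TRUE), "probabilities")[, "active"],
      fallback = function(X, y, seed)
        .withSeed(seed, e1071::svm(X, y, kernel = "linear", cost = 0.1,
                                   probability = TRUE))
    ),
    rf = list(
      fit = function(X, y, seed)
        .withSeed(seed, randomForest::randomForest(X, y, ntree = 300)),
      predict = function(m, X) stats::predict(m, X, type = "prob")[, "active"],
      fallback = function(X, y, seed)
        .withSeed(seed, randomForest::randomForest(X, y, ntree = 300,
                                                   mtry = 1, nodesize = 5))
    ),
    tree = list(
      fit = function(X, y, seed) {
        df <- data.frame(.y = y, X, check.names = FALSE)
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(cp = 0.01, minsplit = 10,
                                                    xval = 0))
      },
      predict = function(m, X)
        stats::predict(m, data.frame(X, check.names = FALSE), type = "prob")[, "active"],
      fallback = function(X, y, seed) {
        df <- data.frame(.y = y, X, check.names = FALSE)
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(cp = 0.05, minsplit = 20,
                                                    maxdepth = 2, xval = 0))
      }
    ),
    nnet = list(
      fit = function(X, y, seed) {
        df <- data.frame(.y = y, X, check.names = FALSE)
        .withSeed(seed, nnet::nnet(.y ~ ., data = df, size = 4, decay = 0.5,
                                   maxit = 300, trace = FALSE))
      },
      predict = function(m, X)
        as.numeric(stats::predict(m, data.frame(X, check.names = FALSE),
                                  type = "raw")),
      fallback = function(X, y, seed) {
        df <- data.frame(.y = y, X, check.names = FALSE)
        .withSeed(seed, nnet::nnet(.y ~ ., data = df, size = 2, decay = 2,
                                   maxit = 300, trace = FALSE))
      }
    ),
    ridgeLogistic = list(
      fit = function(X, y, seed)
        glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                       lambda = c(1, 0.2, 0.05)),
      predict = function(m, X)
        as.numeric(stats::predict(m, X, s = min(m$lambda), type = "response")),
      fallback = function(X, y, seed)
        glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = 1)
    ),
    elasticNet = list(
      fit = function(X, y, seed)
        glmnet::glmnet(X, y, family = "binomial", alpha = 0.5,
                       lambda = c(1, 0.2, 0.05)),
      predict = function(m, X) {
        s <- min(m$lambda)
        as.numeric(stats::predict(m, X, s = s, type = "response"))
      },
      fallback = function(X, y, seed)
        glmnet::glmnet(X, y, family = "binomial", alpha = 0.5, lambda = 0.5)
    )
  )
}

# mclust's MclustDA resolves helper functions in the caller's frame, so fit
# and predict are evaluated in an environment parented by the mclust
# namespace.
.mclustDA <- function(X, y, type = c("MclustDA", "EDDA")) {
  type <- match.arg(type)
  env <- new.env(parent = asNamespace("mclust"))
  env$X <- X; env$y <- y
  m <- if (type == "MclustDA") {
    eval(quote(MclustDA(X, y, G = 1:2, modelNames = c("EII", "VII"),
                        verbose = FALSE)), env)
  } else {
    eval(quote(MclustDA(X, y, modelType = "EDDA", modelNames = "EII",
                        verbose = FALSE)), env)
  }
  .stopIfNot(!is.null(m), "MclustDA returned NULL")
  m
}

.predictMclustDA <- function(m, X) {
  env <- new.env(parent = asNamespace("mclust"))
  env$m <- m; env$X <- X
  z <- eval(quote(predict(m, X)$z), env)
  z[, "active"]
}

# Shrunken-covariance Gaussian discriminant: pooled covariance blended with a
# spherical target, closed-form posteriors. Serves as the regularized
# discriminant learner and as a fallback for the other discriminants.
.fitRegDA <- function(X, y, gamma = 0.3) {
  X <- as.matrix(X)
  lev <- levels(y)
  means <- lapply(lev, function(l) colMeans(X[y == l, , drop = FALSE]))
  names(means) <- lev
  centered <- X - do.call(rbind, means)[as.character(y), , drop = FALSE]
  S <- crossprod(centered) / max(1, nrow(X) - length(lev))
  target <- diag(mean(diag(S)) + 1e-8, ncol(X))
  S_reg <- (1 - gamma) * S + gamma * target
  structure(list(means = means, inv = solve(S_reg),
                 log_prior = log(as.numeric(table(y)[lev]) / nrow(X)),
                 levels = lev),
            class = "regda")
}

.predictRegDA <- function(m, X) {
  X <- as.matrix(X)
  disc <- vapply(seq_along(m$levels), function(i) {
    mu <- m$means[[i]]
    drop(X %*% (m$inv %*% mu)) - 0.5 * drop(t(mu) %*% m$inv %*% mu) + m$log_prior[i]
  }, numeric(nrow(X)))
  if (is.null(dim(disc))) disc <- matrix(disc, nrow = 1)
  disc <- disc - apply(disc, 1, max)
  post <- exp(disc) / rowSums(exp(disc))
  post[, match("active", m$levels)]
}

#' Stratified fold assignment for cross-validation
#'
#' Random partition of the included samples into `k` folds, stratified by
#' class: fold sizes differ by at most one and per-fold class counts differ
#' from perfect proportionality by at most one sample. Deterministic for a
#' fixed seed.
#'
#' @param classes an [ActivityClasses-class].
#' @param k number of folds.
#' @param seed integer seed.
#' @return Named integer vector, sample id -> fold index in `1..k`.
#' @export
assignFolds <- function(classes, k = 10L, seed = 1L) {
  lab <- classLabels(classes)
  k <- as.integer(k)
  .stopIfNot(k >= 2L, "assignFolds: k must be >= 2")
  for (cl in levels(lab)) {
    .stopIfNot(sum(lab == cl) >= k,
               "assignFolds: class '", cl, "' has fewer samples (",
               sum(lab == cl), ") than folds (", k, ")")
  }
  .withSeed(.deriveSeed(seed, 11L), {
    fold <- integer(length(lab))
    names(fold) <- names(lab)
    # one global rotation plus a continuing deal position: per-class counts
    # and total fold sizes both stay within one of each other
    rot <- sample.int(k, 1L) - 1L
    offset <- 0L
    for (cl in levels(lab)) {
      ids <- sample(names(lab)[lab == cl])
      fold[ids] <- ((offset + rot + seq_along(ids) - 1L) %% k) + 1L
      offset <- offset + length(ids)
    }
    fold
  })
}

#' Fold-internal feature selection by two-sample t-test
#'
#' Ranks probes by the ordinary two-sample pooled t-test between the classes
#' computed on the training samples only, and returns the top `m` by p-value
#' (ties: larger |t|, then probe id). The identical list is fed to every
#' learner of that fold; held-out samples are never read.
#'
#' @param cohort a `ColitisCohort` or log2 matrix.
#' @param classes an [ActivityClasses-class].
#' @param training_ids sample ids of the training split.
#' @param m number of probes to select (default 20).
#' @return Character vector of `m` probe ids.
#' @export
selectFoldFeatures <- function(cohort, classes, training_ids, m = 20L) {
  x <- if (methods::is(cohort, "ColitisCohort")) exprsMatrix(cohort) else as.matrix(cohort)
  m <- as.integer(m)
  .stopIfNot(m >= 1L && m <= nrow(x),
             "selectFoldFeatures: m must be in 1..", nrow(x))
  lab <- classLabels(classes)[training_ids]
  .stopIfNot(!anyNA(lab), "selectFoldFeatures: training ids outside the class labels")
  .stopIfNot(all(c("active", "inactive") %in% lab),
             "selectFoldFeatures: both classes must be present in training")
  x <- x[, training_ids, drop = FALSE]
  tt <- .rowPooledT(x, names(lab)[lab == "active"], names(lab)[lab == "inactive"])
  ord <- order(tt$p, -abs(tt$t), rownames(x))
  rownames(x)[ord[seq_len(m)]]
}

#' Fit the learner panel on a training split
#'
#' Standardizes the selected-feature training submatrix (centering/scaling
#' constants are stored and reapplied at scoring time; zero-variance features
#' are left unscaled), then fits every learner in the roster. A learner whose
#' fit errors is refit once with its fallback hyperparameters, else dropped
#' with a warning; if more than half the roster drops, the fold is aborted.
#'
#' @param cohort a `ColitisCohort` or log2 matrix.
#' @param classes an [ActivityClasses-class].
#' @param training_ids training sample ids.
#' @param features probe ids selected for this fold.
#' @param roster learner roster (default [defaultLearnerRoster()]).
#' @param seed integer seed driving the stochastic learners.
#' @return An opaque panel list for [scoreWithPanel()].
#' @export
trainLearnerPanel <- function(cohort, classes, training_ids, features,
                              roster = defaultLearnerRoster(), seed = 1L) {
  x <- if (methods::is(cohort, "ColitisCohort")) exprsMatrix(cohort) else as.matrix(cohort)
  .stopIfNot(length(roster) >= 1L, "trainLearnerPanel: empty roster")
  miss <- setdiff(features, rownames(x))
  .stopIfNot(length(miss) == 0L, "trainLearnerPanel: features absent from matrix: ",
             paste(utils::head(miss, 5), collapse = ", "))
  y <- classLabels(classes)[training_ids]
  X <- t(x[features, training_ids, drop = FALSE])
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")

  fits <- vector("list", length(roster))
  names(fits) <- names(roster)
  for (i in seq_along(roster)) {
    lseed <- .deriveSeed(seed, 101L, i)
    fits[[i]] <- tryCatch(
      roster[[i]]$fit(Xs, y, lseed),
      error = function(e) tryCatch({
        m <- roster[[i]]$fallback(Xs, y, lseed)
        attr(m, "used_fallback") <- TRUE
        m
      }, error = function(e2) {
        warning("learner '", names(roster)[i], "' dropped: ",
                conditionMessage(e2), call. = FALSE)
        NULL
      })
    )
  }
  ok <- !vapply(fits, is.null, logical(1))
  .stopIfNot(sum(ok) > length(roster) / 2,
             "trainLearnerPanel: more than half the roster failed to fit; fold aborted")
  list(features = features, center = center, scale = scale,
       fits = fits[ok], roster = roster[names(fits)[ok]],
       learners = names(roster), seed = as.integer(seed))
}

#' Score samples with a fitted learner panel
#'
#' Applies the panel's stored standardization and returns one probability of
#' active disease per learner per sample. Scores outside \[0, 1\] (beyond
#' numerical tolerance) violate the learner contract and raise an error.
#'
#' @param panel from [trainLearnerPanel()].
#' @param cohort a `ColitisCohort` or log2 matrix.
#' @param sample_ids samples to score.
#' @return Numeric matrix, learners x samples.
#' @export
scoreWithPanel <- function(panel, cohort, sample_ids) {
  x <- if (methods::is(cohort, "ColitisCohort")) exprsMatrix(cohort) else as.matrix(cohort)
  miss <- setdiff(panel$features, rownames(x))
  .stopIfNot(length(miss) == 0L, "scoreWithPanel: missing feature(s): ",
             paste(utils::head(miss, 5), collapse = ", "))
  miss_s <- setdiff(sample_ids, colnames(x))
  .stopIfNot(length(miss_s) == 0L, "scoreWithPanel: missing sample(s): ",
             paste(utils::head(miss_s, 5), collapse = ", "))
  X <- t(x[panel$features, sample_ids, drop = FALSE])
  Xs <- sweep(sweep(X, 2, panel$center), 2, panel$scale, "/")
  out <- matrix(NA_real_, nrow = length(panel$fits), ncol = length(sample_ids),
                dimnames = list(names(panel$fits), sample_ids))
  for (nm in names(panel$fits)) {
    fit <- panel$fits[[nm]]
    # regularized-discriminant fallbacks replace several learners' models
    sc <- if (inherits(fit, "regda")) .predictRegDA(fit, Xs) else
      as.numeric(panel$roster[[nm]]$predict(fit, Xs))
    sc <- as.numeric(sc)
    .stopIfNot(length(sc) == length(sample_ids) && !anyNA(sc),
               "scoreWithPanel: learner '", nm, "' returned invalid scores")
    .stopIfNot(all(sc > -1e-6 & sc < 1 + 1e-6),
               "scoreWithPanel: learner '", nm, "' returned scores outside [0, 1]")
    out[nm, ] <- pmin(1, pmax(0, sc))
  }
  out
}

#' Median-ensemble score
#'
#' Per-sample median across the learner scores (even learner counts average
#' the central pair). Invariant to learner order.
#'
#' @param scores learners x samples matrix from [scoreWithPanel()].
#' @return Named numeric vector of ensemble scores.
#' @export
ensembleMedian <- function(scores) {
  .stopIfNot(is.matrix(scores) && nrow(scores) >= 1L,
             "ensembleMedian: need a learners x samples matrix with >= 1 learner")
  .stopIfNot(all(colSums(!is.na(scores)) >= 1L),
             "ensembleMedian: some sample has no learner score")
  apply(scores, 2, stats::median, na.rm = TRUE)
}

#' Cross-validated ensemble classifier
#'
#' Stratified k-fold cross-validation of the median-of-12 ensemble: for each
#' fold, the top-`m` probe sets are selected by t-test on the 90% training
#' split only, the learner panel is fit on those features, and the held-out
#' 10% is scored — so every sample receives exactly one out-of-fold score per
#' learner, from a fold that never saw it. The pooled out-of-fold ensemble
#' scores yield the Mann-Whitney AUC.
#'
#' @param cohort a `ColitisCohort` or log2 matrix.
#' @param classes an [ActivityClasses-class].
#' @param k folds (default 10).
#' @param seed integer seed (folds + stochastic learners).
#' @param roster learner roster.
#' @param n_features probes selected per fold (default 20).
#' @return A [CrossValidationResult-class].
#' @export
crossValidate <- function(cohort, classes, k = 10L, seed = 1L,
                          roster = defaultLearnerRoster(), n_features = 20L) {
  x <- if (methods::is(cohort, "ColitisCohort")) exprsMatrix(cohort) else as.matrix(cohort)
  lab <- classLabels(classes)
  fold <- assignFolds(classes, k = k, seed = seed)
  ids <- names(fold)
  learner_names <- names(roster)
  score_mat <- matrix(NA_real_, nrow = length(learner_names), ncol = length(ids),
                      dimnames = list(learner_names, ids))
  features <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- ids[fold == f]
    train_ids <- ids[fold != f]
    features[[f]] <- selectFoldFeatures(x, classes, train_ids, m = n_features)
    panel <- trainLearnerPanel(x, classes, train_ids, features[[f]],
                               roster = roster, seed = .deriveSeed(seed, 7L, f))
    sc <- scoreWithPanel(panel, x, test_ids)
    score_mat[rownames(sc), test_ids] <- sc
  }
  ens <- ensembleMedian(score_mat[!apply(is.na(score_mat), 1, all), , drop = FALSE])
  scores <- data.frame(
    sample_id = ids,
    fold = as.integer(fold),
    class = as.character(lab[ids]),
    t(score_mat),
    ensemble = ens[ids],
    check.names = FALSE,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  auc <- aucMannWhitney(scores$ensemble, scores$class == "active")
  methods::new("CrossValidationResult", scores = scores, features = features,
               auc = auc, seed = as.integer(seed), tag = cohortTag(classes),
               learners = learner_names)
}

#' Refit the ensemble on all included samples
#'
#' Deployment refit: features are selected on the full included cohort (the
#' selection is a deterministic t-test ranking, hence seed-free) and the
#' panel is refit on all samples. The returned model can be serialized with
#' [saveClassifierModel()] and scores new biopsies via [predictClassifier()].
#'
#' @inheritParams crossValidate
#' @return A [ClassifierModel-class].
#' @export
fitFinalClassifier <- function(cohort, classes, roster = defaultLearnerRoster(),
                               seed = 1L, n_features = 20L) {
  x <- if (methods::is(cohort, "ColitisCohort")) exprsMatrix(cohort) else as.matrix(cohort)
  ids <- includedSamples(classes)
  features <- selectFoldFeatures(x, classes, ids, m = n_features)
  panel <- trainLearnerPanel(x, classes, ids, features, roster = roster,
                             seed = .deriveSeed(seed, 7L, 0L))
  methods::new("ClassifierModel", features = features, panel = panel,
               tag = cohortTag(classes), seed = as.integer(seed))
}

#' Score biopsies with a fitted ClassifierModel
#'
#' @param model a [ClassifierModel-class].
#' @param cohort a `ColitisCohort` or log2 matrix carrying all model features.
#' @param sample_ids samples to score (default: all columns).
#' @return List with `learner_scores` (learners x samples) and `ensemble`
#'   (named vector).
#' @export
predictClassifier <- function(model, cohort, sample_ids = NULL) {
  .stopIfNot(methods::is(model, "ClassifierModel"), "predictClassifier: not a ClassifierModel")
  x <- if (methods::is(cohort, "ColitisCohort")) exprsMatrix(cohort) else as.matrix(cohort)
  if (is.null(sample_ids)) sample_ids <- colnames(x)
  sc <- scoreWithPanel(model@panel, x, sample_ids)
  list(learner_scores = sc, ensemble = ensembleMedian(sc))
}

#' Save / load a ClassifierModel
#'
#' Serialization round-trips exactly: a reloaded model produces identical
#' scores.
#'
#' @param model a [ClassifierModel-class].
#' @param path file path.
#' @return `saveClassifierModel` invisibly returns `path`;
#'   `loadClassifierModel` returns the model.
#' @export
saveClassifierModel <- function(model, path) {
  .stopIfNot(methods::is(model, "ClassifierModel"), "saveClassifierModel: not a ClassifierModel")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveClassifierModel
#' @export
loadClassifierModel <- function(path) {
  model <- readRDS(path)
  .stopIfNot(methods::is(model, "ClassifierModel"),
             "loadClassifierModel: file does not contain a ClassifierModel")
  model
}
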