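#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks (midranks) for ties; `rho` is the Pearson correlation of the
#' midranks and the two-sided p comes from the t-approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} df. Incomplete pairs
#' are dropped and the n used is reported. A constant vector makes `rho`
#' undefined: an explicit `undefined` marker is returned, never 0.
#'
#' @param x,y paired numeric vectors.
#' @return List: `rho`, `p`, `n`, `undefined`.
#' @export
spearmanTest <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  .stopIfNot(n >= 4L, "spearmanTest: need >= 4 complete pairs (got ", n, ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (1 - abs(rho) < 1e-12) {
    rho <- sign(rho)
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p, n = n, undefined = FALSE)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' two-sided p (delegates to [stats::t.test()]). Both groups degenerate
#' (zero variance) is an error.
#'
#' @param a,b numeric group vectors (each n >= 2).
#' @return List: `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
welchTest <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  .stopIfNot(length(a) >= 2L && length(b) >= 2L, "welchTest: each group needs >= 2 values")
  .stopIfNot(stats::var(a) > 0 || stats::var(b) > 0,
             "welchTest: degenerate (zero) variance in both groups")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_a = mean(a), mean_b = mean(b), n_a = length(a), n_b = length(b))
}

#' Rank-based (Mann-Whitney) AUC
#'
#' \eqn{\mathrm{AUC} = P(S_+ > S_-) + \tfrac12 P(S_+ = S_-)} computed from
#' midranks; identical scores give 0.5 exactly, and any strictly monotone
#' transform of the scores leaves the AUC unchanged.
#'
#' @param scores numeric scores.
#' @param labels logical (or coercible) positive-class indicator.
#' @return The AUC in \[0, 1\].
#' @export
aucMannWhitney <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  .stopIfNot(n1 >= 1L && n0 >= 1L, "aucMannWhitney: both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Assemble the per-sample predictor table for the outcome battery
#'
#' One row per diseased biopsy: the out-of-fold `Mayo_Prob_1` / `Mayo_Prob_2`
#' ensemble scores, `MCalpro`, the clinical covariates, and the binary
#' outcome `poor_outcome = 1[status_code > 1]` (`NA` without follow-up).
#' Samples absent from a classifier's cohort (e.g. IBDU under `Mayo_Prob_1`)
#' carry `NA` for that score; each downstream statistic is complete-case and
#' reports its n.
#'
#' @param cohort a `ColitisCohort`.
#' @param cv1,cv2 [CrossValidationResult-class] objects for the two cohorts
#'   (either may be `NULL`).
#' @param mcalpro named MCalpro vector from [mcalproScore()] (optional).
#' @param status_threshold poor outcome is `status_code > status_threshold`
#'   (default 1, the convention used throughout).
#' @return A `data.frame` keyed by `sample_id`.
#' @export
buildPredictorTable <- function(cohort, cv1 = NULL, cv2 = NULL, mcalpro = NULL,
                                status_threshold = 1L) {
  samples <- sampleInfo(cohort)
  dis <- samples[samples$diagnosis != "control", , drop = FALSE]
  out <- data.frame(
    sample_id = rownames(dis),
    mayo_prob_1 = NA_real_,
    mayo_prob_2 = NA_real_,
    mcalpro = NA_real_,
    endoscopic_mayo = dis$endoscopic_mayo,
    partial_mayo = dis$partial_mayo,
    total_mayo = dis$total_mayo,
    pga = dis$pga,
    fecal_calprotectin = dis$fecal_calprotectin,
    poor_outcome = ifelse(is.na(dis$status_code), NA_integer_,
                          as.integer(dis$status_code > status_threshold)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  if (!is.null(cv1)) {
    sc <- cvScores(cv1)
    out$mayo_prob_1 <- sc$ensemble[match(out$sample_id, sc$sample_id)]
  }
  if (!is.null(cv2)) {
    sc <- cvScores(cv2)
    out$mayo_prob_2 <- sc$ensemble[match(out$sample_id, sc$sample_id)]
  }
  if (!is.null(mcalpro)) {
    out$mcalpro <- unname(mcalpro[out$sample_id])
  }
  out
}

# Ridge-penalized logistic regression by IRLS (intercept unpenalized);
# returns the Wald p of the slope. Used as the separation fallback.
.ridgeLogisticWald <- function(x, y, lambda = 0.5) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  pen <- diag(c(0, lambda))
  for (i in seq_len(100)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  cov <- solve(crossprod(X, X * w) + pen)
  z <- beta[2] / sqrt(cov[2, 2])
  2 * stats::pnorm(-abs(z))
}

#' Univariate logistic screen of each predictor against poor outcome
#'
#' Per predictor: a maximum-likelihood logistic fit (intercept + predictor)
#' on complete cases, the Wald p of the slope, and the Mann-Whitney AUC of
#' the raw predictor (equal to the AUC of the fitted probabilities, a
#' monotone transform). Perfect separation is flagged and the p replaced by a
#' ridge-penalized Wald fallback; constant predictors return an explicit
#' `undefined` flag.
#'
#' @param predictors from [buildPredictorTable()].
#' @param columns predictor columns to screen (default: all score and
#'   clinical columns).
#' @return A `data.frame`: `predictor`, `n`, `p`, `auc`, `flag`.
#' @export
singlePredictorScreen <- function(predictors,
                                  columns = c("mayo_prob_1", "mayo_prob_2",
                                              "mcalpro", "endoscopic_mayo",
                                              "partial_mayo", "total_mayo",
                                              "pga", "fecal_calprotectin")) {
  .stopIfNot("poor_outcome" %in% colnames(predictors),
             "singlePredictorScreen: predictors must carry poor_outcome")
  columns <- intersect(columns, colnames(predictors))
  rows <- lapply(columns, function(col) {
    x <- predictors[[col]]
    y <- predictors$poor_outcome
    ok <- is.finite(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 4L || stats::sd(x) == 0 || length(unique(y)) < 2L) {
      return(data.frame(predictor = col, n = n, p = NA_real_, auc = NA_real_,
                        flag = "undefined", stringsAsFactors = FALSE))
    }
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ x, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep <<- TRUE
        }
        invokeRestart("muffleWarning")
      }
    )
    p <- summary(fit)$coefficients["x", "Pr(>|z|)"]
    flag <- ""
    if (sep || abs(stats::coef(fit)[["x"]]) * stats::sd(x) > 15) {
      flag <- "separation"
      p <- .ridgeLogisticWald(scale(x)[, 1], y)
    }
    data.frame(predictor = col, n = n, p = p,
               auc = aucMannWhitney(x, y == 1L), flag = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Likelihood-ratio comparison of nested logistic outcome models
#'
#' Fits reduced and full logistic models of poor outcome on the complete
#' cases shared by both covariate lists and compares them with the
#' likelihood-ratio test: \eqn{\Lambda = 2(\ell_{full} - \ell_{reduced})},
#' p from the chi-square upper tail with df = the added parameter count
#' (model-rank difference, so aliased copies add nothing). AUCs of both
#' models' fitted probabilities are reported.
#'
#' @param predictors from [buildPredictorTable()].
#' @param reduced,full character vectors of covariate columns; `full` must
#'   contain every `reduced` covariate.
#' @return List: `reduced`, `full`, `loglik_reduced`, `loglik_full`, `lrt`,
#'   `df`, `p`, `auc_reduced`, `auc_full`, `n`.
#' @export
likelihoodRatioCompare <- function(predictors, reduced, full) {
  .stopIfNot(all(reduced %in% full),
             "likelihoodRatioCompare: models not nested (reduced must be a subset of full)")
  .stopIfNot(all(full %in% colnames(predictors)),
             "likelihoodRatioCompare: unknown covariate(s): ",
             paste(setdiff(full, colnames(predictors)), collapse = ", "))
  dat <- predictors[, unique(c("poor_outcome", full)), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  .stopIfNot(nrow(dat) >= length(full) + 2L,
             "likelihoodRatioCompare: too few complete cases (", nrow(dat), ")")
  .stopIfNot(length(unique(dat$poor_outcome)) == 2L,
             "likelihoodRatioCompare: outcome is constant on the complete cases")
  f_red <- stats::as.formula(paste("poor_outcome ~",
                                   if (length(reduced)) paste(reduced, collapse = " + ") else "1"))
  f_full <- stats::as.formula(paste("poor_outcome ~", paste(full, collapse = " + ")))
  m_red <- stats::glm(f_red, family = stats::binomial(), data = dat)
  m_full <- stats::glm(f_full, family = stats::binomial(), data = dat)
  .stopIfNot(m_red$converged && m_full$converged,
             "likelihoodRatioCompare: logistic fit did not converge")
  ll_r <- as.numeric(stats::logLik(m_red))
  ll_f <- as.numeric(stats::logLik(m_full))
  lrt <- max(0, 2 * (ll_f - ll_r))
  df <- m_full$rank - m_red$rank
  p <- if (df <= 0) 1 else stats::pchisq(lrt, df, lower.tail = FALSE)
  list(reduced = reduced, full = full,
       loglik_reduced = ll_r, loglik_full = ll_f,
       lrt = lrt, df = df, p = p,
       auc_reduced = aucMannWhitney(stats::fitted(m_red), dat$poor_outcome == 1L),
       auc_full = aucMannWhitney(stats::fitted(m_full), dat$poor_outcome == 1L),
       n = nrow(dat))
}

#' Random-forest permutation importance by out-of-bag AUC decrease
#'
#' Fits a probability random forest (500 trees, sqrt(p) features per split)
#' of poor outcome on the complete cases, evaluates the out-of-bag AUC, then
#' permutes each predictor `n_permutations` times and records the mean
#' decrease in out-of-bag AUC — an importance measure comparable across
#' mixed-scale predictors. Deterministic for a fixed seed; invariant to
#' predictor column order.
#'
#' @param predictors from [buildPredictorTable()].
#' @param columns predictor columns to rank (default as in
#'   [singlePredictorScreen()]).
#' @param n_permutations permutations per predictor (default 50).
#' @param num_trees forest size (default 500).
#' @param seed integer seed.
#' @return A `data.frame` sorted by decreasing importance: `predictor`,
#'   `importance` (mean OOB AUC decrease), `rank`, with attributes
#'   `baseline_auc` and `n`.
#' @export
permutationImportance <- function(predictors,
                                  columns = c("mayo_prob_1", "mayo_prob_2",
                                              "mcalpro", "endoscopic_mayo",
                                              "partial_mayo", "total_mayo",
                                              "fecal_calprotectin"),
                                  n_permutations = 50L, num_trees = 500L,
                                  seed = 1L) {
  columns <- sort(intersect(columns, colnames(predictors)))
  .stopIfNot(length(columns) >= 2L, "permutationImportance: need >= 2 predictors")
  dat <- predictors[, c("poor_outcome", columns), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  .stopIfNot(nrow(dat) >= 20L, "permutationImportance: fewer than 20 complete cases (",
             nrow(dat), ")")
  .stopIfNot(length(unique(dat$poor_outcome)) == 2L,
             "permutationImportance: outcome is constant on the complete cases")
  y <- factor(ifelse(dat$poor_outcome == 1L, "poor", "good"),
              levels = c("good", "poor"))
  X <- dat[, columns, drop = FALSE]
  rf <- ranger::ranger(x = X, y = y, probability = TRUE,
                       num.trees = as.integer(num_trees),
                       mtry = max(1L, floor(sqrt(length(columns)))),
                       keep.inbag = TRUE, seed = .deriveSeed(seed, 31L),
                       num.threads = 1)
  inbag <- do.call(cbind, rf$inbag.counts)      # n x trees
  oob <- inbag == 0
  .stopIfNot(all(rowSums(oob) > 0), "permutationImportance: sample never out-of-bag; increase num_trees")
  poor_col <- match("poor", colnames(rf$predictions))

  oobAUC <- function(newX) {
    pr <- stats::predict(rf, data = newX, predict.all = TRUE,
                         num.threads = 1)$predictions[, poor_col, ]
    scores <- rowSums(pr * oob) / rowSums(oob)
    aucMannWhitney(scores, y == "poor")
  }
  baseline <- oobAUC(X)
  imp <- vapply(columns, function(col) {
    drops <- vapply(seq_len(n_permutations), function(r) {
      Xp <- X
      Xp[[col]] <- .withSeed(.deriveSeed(seed, 97L, match(col, columns), r),
                             sample(Xp[[col]]))
      baseline - oobAUC(Xp)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  out <- data.frame(predictor = columns, importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$predictor), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "baseline_auc") <- baseline
  attr(out, "n") <- nrow(dat)
  out
}
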