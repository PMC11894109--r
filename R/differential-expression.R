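#' Empirical-Bayes moderated t-test against the activity classes
#'
#' Fits, per probe set, the two-group comparison of log2 expression between
#' active and inactive biopsies using an empirical-Bayes moderated t-statistic:
#' the per-probe residual variance \eqn{s_g^2} (pooled, \eqn{d_g} df) is
#' shrunk toward a prior \eqn{s_0^2} estimated by moment matching a scaled
#' inverse-chi-square distribution to the observed variances on the
#' log scale, giving the posterior variance
#' \deqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}
#' and \eqn{t_g = \Delta\bar x_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})} on
#' \eqn{d_0 + d_g} degrees of freedom. Two-sided p-values are adjusted by
#' Benjamini-Hochberg. Control samples never enter the test; they contribute
#' only the `mean_control` column. Group means are reported as linear-scale
#' geometric means, i.e. `2^(mean log2)`.
#'
#' Probes with zero variance across all tested samples are flagged
#' (`zero_variance`); when their group means also coincide they get `t = 0`,
#' `p = 1`.
#'
#' @param cohort a `ColitisCohort` (or a log2 matrix with probe rownames).
#' @param classes an [ActivityClasses-class] from [defineActivityClasses()].
#' @param control_ids sample ids of the control biopsies used for
#'   `mean_control` (default: the cohort's controls; ignored for plain
#'   matrices unless given).
#' @param prior_df optional override of the estimated prior df \eqn{d_0}
#'   (`0` gives the ordinary pooled t-test, `Inf` full shrinkage); mainly for
#'   validation.
#' @return A `data.frame` (one row per probe): `probe_id`, `gene_symbol`,
#'   `mean_active`, `mean_inactive`, `mean_control`, `log2_fold_change`
#'   (active - inactive), `t_moderated`, `p_unadjusted`, `p_fdr`,
#'   `zero_variance`, with the estimated `prior_df` / `prior_var` as
#'   attributes (`"moderation"`).
#' @export
fitModeratedT <- function(cohort, classes, control_ids = NULL, prior_df = NULL) {
  if (methods::is(cohort, "ColitisCohort")) {
    x <- exprsMatrix(cohort)
    gene <- probeInfo(cohort)$gene_symbol
    if (is.null(control_ids)) control_ids <- controlSamples(cohort)
  } else {
    x <- as.matrix(cohort)
    gene <- rep(NA_character_, nrow(x))
    if (is.null(control_ids)) control_ids <- character(0)
  }
  lab <- classLabels(classes)
  .stopIfNot(all(names(lab) %in% colnames(x)),
             "fitModeratedT: class samples absent from matrix: ",
             paste(utils::head(setdiff(names(lab), colnames(x)), 5), collapse = ", "))
  act <- names(lab)[lab == "active"]
  ina <- names(lab)[lab == "inactive"]
  .stopIfNot(length(act) >= 2L && length(ina) >= 2L,
             "fitModeratedT: need >= 2 samples per class")

  tt <- .rowPooledT(x, act, ina)
  s2 <- tt$s2
  df <- tt$df
  zero_var <- s2 <= 0

  if (is.null(prior_df)) {
    mod <- .fitVariancePrior(s2[!zero_var], df)
  } else {
    s0 <- if (any(!zero_var)) stats::median(s2[!zero_var]) else 1
    mod <- list(prior_df = as.numeric(prior_df), prior_var = s0)
  }
  d0 <- mod$prior_df
  s02 <- mod$prior_var

  post_s2 <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + df * s2) / (d0 + df)
  se <- sqrt(post_s2 * (1 / tt$n_a + 1 / tt$n_b))
  delta <- tt$mean_a - tt$mean_b
  t_mod <- ifelse(se > 0, delta / se, 0)
  df_total <- d0 + df
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t_mod), df_total), 1)

  mean_control <- if (length(control_ids)) {
    2^rowMeans(x[, control_ids, drop = FALSE])
  } else rep(NA_real_, nrow(x))

  de <- data.frame(
    probe_id = rownames(x),
    gene_symbol = gene,
    mean_active = 2^tt$mean_a,
    mean_inactive = 2^tt$mean_b,
    mean_control = mean_control,
    log2_fold_change = delta,
    t_moderated = t_mod,
    p_unadjusted = p,
    p_fdr = benjaminiHochberg(p),
    zero_variance = zero_var,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(de, "moderation") <- list(prior_df = d0, prior_var = s02,
                                 residual_df = df,
                                 n_active = tt$n_a, n_inactive = tt$n_b)
  de
}

# Moment-match a scaled inverse-chi-square prior to observed residual
# variances via the log-variance distribution (digamma/trigamma identities).
.fitVariancePrior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2L) return(list(prior_df = 0, prior_var = if (length(s2)) s2 else 1))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    # observed variances no more dispersed than chi-square sampling noise:
    # infinite prior df, all shrink to the common (pooled arithmetic-mean)
    # variance
    return(list(prior_df = Inf, prior_var = mean(s2)))
  }
  d0 <- 2 * .trigammaInverse(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(prior_df = d0, prior_var = s02)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjustment: with order statistics \eqn{p_{(1)} \le \dots \le
#' p_{(m)}}, the adjusted value is \eqn{\min_{j \ge i} (m/j)\, p_{(j)}},
#' capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
benjaminiHochberg <- function(p) {
  .stopIfNot(is.numeric(p) && length(p) >= 1L, "benjaminiHochberg: p must be numeric")
  .stopIfNot(!anyNA(p) && all(p >= 0 & p <= 1),
             "benjaminiHochberg: p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Rank transcripts by association strength
#'
#' Filters probes changed in the requested direction (sign of the active -
#' inactive log2 fold change), sorts by unadjusted p ascending with ties
#' broken by larger absolute fold change and then lexicographic probe id, and
#' optionally collapses to unique transcripts by keeping each gene's
#' best-ranked probe set.
#'
#' @param de a `data.frame` from [fitModeratedT()].
#' @param direction `"increased"` or `"decreased"`.
#' @param k number of entries to return.
#' @param collapse_to_genes keep only each gene symbol's best probe set?
#' @return The first `k` rows of the ranked table (fewer if the direction has
#'   fewer probes).
#' @export
rankTranscripts <- function(de, direction = c("increased", "decreased"),
                            k = 30L, collapse_to_genes = FALSE) {
  direction <- match.arg(direction)
  .stopIfNot(nrow(de) > 0, "rankTranscripts: empty DE table")
  .stopIfNot(is.numeric(k) && k > 0, "rankTranscripts: k must be > 0")
  keep <- if (direction == "increased") de$log2_fold_change > 0 else de$log2_fold_change < 0
  sub <- de[keep, , drop = FALSE]
  if (!nrow(sub)) return(sub)
  ord <- order(sub$p_unadjusted, -abs(sub$log2_fold_change), sub$probe_id)
  sub <- sub[ord, , drop = FALSE]
  if (collapse_to_genes) {
    gene <- sub$gene_symbol
    # probes without a symbol are kept individually
    key <- ifelse(is.na(gene) | gene == "", paste0(".probe:", sub$probe_id), gene)
    sub <- sub[!duplicated(key), , drop = FALSE]
  }
  utils::head(sub, as.integer(k))
}

#' Volcano-plot table
#'
#' Per probe: `log2_fold_change` on x, `-log10(p_unadjusted)` on y, the
#' annotation interest-set flag, and a marker (`fdr_line`) on the probe with
#' the largest p-value still satisfying `p_fdr < 0.05` — the height of the
#' FDR line. If nothing passes FDR the marker is absent everywhere.
#'
#' @param de a `data.frame` from [fitModeratedT()].
#' @param cohort optional `ColitisCohort` supplying interest-set flags.
#' @return A `data.frame`: `probe_id`, `gene_symbol`, `log2_fold_change`,
#'   `neg_log10_p`, `flag`, `fdr_line`.
#' @export
volcanoTable <- function(de, cohort = NULL) {
  flag <- rep("", nrow(de))
  if (!is.null(cohort) && methods::is(cohort, "ColitisCohort")) {
    ann <- probeInfo(cohort)
    flag <- ann$flags[match(de$probe_id, ann$probe_id)]
    flag[is.na(flag)] <- ""
  }
  fdr_line <- rep(FALSE, nrow(de))
  hit <- which(de$p_fdr < 0.05)
  if (length(hit)) fdr_line[hit[which.max(de$p_unadjusted[hit])]] <- TRUE
  data.frame(
    probe_id = de$probe_id,
    gene_symbol = de$gene_symbol,
    log2_fold_change = de$log2_fold_change,
    neg_log10_p = -log10(de$p_unadjusted),
    flag = flag,
    fdr_line = fdr_line,
    stringsAsFactors = FALSE
  )
}
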