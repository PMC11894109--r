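#' Standardize expression against the control population
#'
#' Per probe \eqn{g} and sample \eqn{s}, the standardized value is
#' \deqn{2^{\,x_{gs} - \overline{x}_{g,\mathrm{ctl}}}}
#' i.e. the linear-scale fold over the control geometric mean. By
#' construction the per-probe geometric mean over the controls themselves is
#' exactly 1. A z-score variant (`method = "zscore"`, log2 residuals divided
#' by the control SD) is available for sensitivity analysis; note geometric
#' means are ill-defined on z-scores, so the default fold scale is what
#' [transcriptSetScore()] expects.
#'
#' @param cohort a `ColitisCohort` or log2 matrix.
#' @param control_ids control sample ids (default: the cohort's controls);
#'   at least 2 required.
#' @param method `"fold"` (default) or `"zscore"`.
#' @return Numeric matrix, probes x samples, on the linear fold scale (or
#'   z-score scale).
#' @export
standardizeToControls <- function(cohort, control_ids = NULL,
                                  method = c("fold", "zscore")) {
  method <- match.arg(method)
  if (methods::is(cohort, "ColitisCohort")) {
    x <- exprsMatrix(cohort)
    if (is.null(control_ids)) control_ids <- controlSamples(cohort)
  } else {
    x <- as.matrix(cohort)
  }
  .stopIfNot(length(control_ids) >= 2L,
             "standardizeToControls: need >= 2 control samples")
  miss <- setdiff(control_ids, colnames(x))
  .stopIfNot(length(miss) == 0L, "standardizeToControls: unknown control id(s): ",
             paste(utils::head(miss, 5), collapse = ", "))
  ctl_mean <- rowMeans(x[, control_ids, drop = FALSE])
  centered <- x - ctl_mean
  if (method == "fold") return(2^centered)
  ctl_sd <- apply(x[, control_ids, drop = FALSE], 1, stats::sd)
  ctl_sd[ctl_sd == 0] <- 1
  centered / ctl_sd
}

#' Transcript-set score: geometric mean of control-standardized expression
#'
#' A transcript set is a user-chosen list of probe sets representing a
#' biology of interest. Its per-sample score is the geometric mean, across
#' the set's probes, of the control-standardized (fold-over-control) values —
#' so a score of 2 means the set averages 2-fold the control geometric mean.
#' A single-probe set returns that probe's standardized value unchanged, and
#' the geometric mean of any set's scores over the control population is 1.
#'
#' @param standardized probes x samples matrix from
#'   [standardizeToControls()] (fold scale).
#' @param probe_ids probe ids of the set (>= 1, present in the matrix).
#' @return Named numeric score vector, one per sample.
#' @export
transcriptSetScore <- function(standardized, probe_ids) {
  .stopIfNot(length(probe_ids) >= 1L, "transcriptSetScore: empty transcript set")
  miss <- setdiff(probe_ids, rownames(standardized))
  .stopIfNot(length(miss) == 0L, "transcriptSetScore: probe(s) not in matrix: ",
             paste(utils::head(miss, 5), collapse = ", "))
  sub <- standardized[probe_ids, , drop = FALSE]
  .stopIfNot(all(sub > 0), "transcriptSetScore: standardized values must be positive (fold scale)")
  if (length(probe_ids) == 1L) return(sub[1, ])  # identity, exactly
  2^colMeans(log2(sub))
}

#' Molecular calprotectin score (MCalpro)
#'
#' The geometric mean of the control-standardized expression of the
#' S100A8 and S100A9 probe sets (the calprotectin heterodimer subunits) —
#' a tissue-level analogue of fecal calprotectin. Probes are looked up in the
#' cohort annotation by gene symbol; every probe mapping to either gene
#' enters the set.
#'
#' @param cohort a `ColitisCohort` with S100A8/S100A9 annotated probes.
#' @param control_ids control ids (default: the cohort's controls).
#' @return Named numeric vector of MCalpro scores (all samples).
#' @export
mcalproScore <- function(cohort, control_ids = NULL) {
  .stopIfNot(methods::is(cohort, "ColitisCohort"), "mcalproScore: not a ColitisCohort")
  ann <- probeInfo(cohort)
  probes <- ann$probe_id[ann$gene_symbol %in% c("S100A8", "S100A9")]
  .stopIfNot(length(probes) >= 1L,
             "mcalproScore: no probes annotated S100A8/S100A9 in the cohort")
  std <- standardizeToControls(cohort, control_ids = control_ids)
  transcriptSetScore(std, probes)
}
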