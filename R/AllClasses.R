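#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.REQUIRED_SAMPLE_FIELDS <- c(
  "patient_id", "diagnosis", "endoscopic_mayo", "partial_mayo", "total_mayo",
  "pga", "fecal_calprotectin", "labeling_kit", "center", "status_code"
)

#' ColitisCohort: expression matrix plus clinical covariates
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a probe-set
#' x sample log2 expression matrix (assay `"exprs"`), the clinical sample
#' table in `colData`, and the probe-to-gene annotation in `rowData`. Cohorts
#' produced by [simulateCohort()] additionally carry the planted ground truth
#' in `metadata(x)$truth` (see [cohortTruth()]).
#'
#' The clinical table must contain `patient_id`, `diagnosis` (one of `"UC"`,
#' `"IBDU"`, `"control"`), `endoscopic_mayo` (0-3, `NA` for controls),
#' `partial_mayo` (0-9), `total_mayo` (0-12), `pga` (0-3),
#' `fecal_calprotectin` (ug/g, `NA` allowed), `labeling_kit` (`"kit_A"` or
#' `"kit_B"`), `center`, and `status_code` (0-3 outcome grade, `NA` allowed).
#' Controls carry no Mayo grading and no status code; every diseased sample
#' must have an endoscopic Mayo subscore.
#'
#' @export
setClass("ColitisCohort", contains = "SummarizedExperiment")

setValidity("ColitisCohort", function(object) {
  msg <- character(0)
  if (!"exprs" %in% assayNames(object)) {
    return("assay 'exprs' (log2 expression) is required")
  }
  x <- assay(object, "exprs")
  if (anyNA(x) || !all(is.finite(x))) {
    bad <- colnames(x)[colSums(!is.finite(x)) > 0]
    msg <- c(msg, paste0("non-finite expression values in sample(s): ",
                         paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (anyDuplicated(rownames(object))) {
    msg <- c(msg, "duplicated probe ids")
  }
  if (anyDuplicated(colnames(object))) {
    msg <- c(msg, "duplicated sample ids")
  }
  cd <- colData(object)
  missing_fields <- setdiff(.REQUIRED_SAMPLE_FIELDS, colnames(cd))
  if (length(missing_fields)) {
    return(paste0("missing sample fields: ", paste(missing_fields, collapse = ", ")))
  }
  if (!all(cd$diagnosis %in% c("UC", "IBDU", "control"))) {
    msg <- c(msg, "diagnosis must be UC, IBDU or control")
  }
  ctrl <- cd$diagnosis == "control"
  if (any(!is.na(cd$endoscopic_mayo[ctrl])) || any(!is.na(cd$status_code[ctrl]))) {
    msg <- c(msg, "controls must have missing endoscopic_mayo and status_code")
  }
  if (any(is.na(cd$endoscopic_mayo[!ctrl]))) {
    bad <- rownames(cd)[!ctrl & is.na(cd$endoscopic_mayo)]
    msg <- c(msg, paste0("diseased sample(s) without endoscopic_mayo: ",
                         paste(utils::head(bad, 5), collapse = ", ")))
  }
  em <- cd$endoscopic_mayo[!ctrl]
  if (length(em) && !all(em %in% 0:3)) {
    msg <- c(msg, "endoscopic_mayo must be in 0..3")
  }
  if (!"gene_symbol" %in% colnames(rowData(object))) {
    msg <- c(msg, "rowData must contain gene_symbol")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ColitisCohort
#'
#' @param exprs numeric matrix of log2 intensities, probes in rows (rownames =
#'   probe ids), samples in columns (colnames = sample ids).
#' @param samples `data.frame` of clinical covariates, one row per sample; a
#'   `sample_id` column or rownames must match `colnames(exprs)`.
#' @param annotation `data.frame` with `probe_id`, `gene_symbol`, and optional
#'   `flags` (semicolon-delimited interest-set tags) covering every probe.
#' @param truth optional planted-truth list from the simulator.
#' @return A [ColitisCohort-class] object.
#' @export
ColitisCohort <- function(exprs, samples, annotation, truth = NULL) {
  exprs <- as.matrix(exprs)
  samples <- as.data.frame(samples)
  if ("sample_id" %in% colnames(samples)) {
    rownames(samples) <- as.character(samples$sample_id)
    samples$sample_id <- NULL
  }
  if (!setequal(rownames(samples), colnames(exprs))) {
    only_m <- setdiff(colnames(exprs), rownames(samples))
    only_s <- setdiff(rownames(samples), colnames(exprs))
    stop("matrix/sample-table id mismatch; only in matrix: [",
         paste(only_m, collapse = ", "), "]; only in sample table: [",
         paste(only_s, collapse = ", "), "]")
  }
  samples <- samples[colnames(exprs), , drop = FALSE]
  annotation <- as.data.frame(annotation)
  if (!"probe_id" %in% colnames(annotation)) {
    stop("annotation requires a probe_id column")
  }
  if (anyDuplicated(annotation$probe_id)) {
    stop("duplicated probe ids in annotation: ",
         paste(utils::head(unique(annotation$probe_id[duplicated(annotation$probe_id)]), 5),
               collapse = ", "))
  }
  miss <- setdiff(rownames(exprs), annotation$probe_id)
  if (length(miss)) {
    stop("probes without annotation row: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  rownames(annotation) <- annotation$probe_id
  annotation <- annotation[rownames(exprs), setdiff(colnames(annotation), "probe_id"),
                           drop = FALSE]
  if (!"flags" %in% colnames(annotation)) annotation$flags <- ""
  se <- SummarizedExperiment(
    assays = list(exprs = exprs),
    colData = DataFrame(samples),
    rowData = DataFrame(annotation)
  )
  obj <- methods::new("ColitisCohort", se)
  if (!is.null(truth)) metadata(obj)$truth <- truth
  obj
}

#' @describeIn ColitisCohort-class log2 expression matrix accessor
#' @param x a `ColitisCohort`
#' @export
exprsMatrix <- function(x) {
  stopifnot(methods::is(x, "ColitisCohort"))
  assay(x, "exprs")
}

#' @describeIn ColitisCohort-class clinical sample table as a data.frame
#' @export
sampleInfo <- function(x) {
  stopifnot(methods::is(x, "ColitisCohort"))
  as.data.frame(colData(x))
}

#' @describeIn ColitisCohort-class probe annotation as a data.frame
#' @export
probeInfo <- function(x) {
  stopifnot(methods::is(x, "ColitisCohort"))
  df <- as.data.frame(rowData(x))
  df$probe_id <- rownames(df)
  df[, c("probe_id", setdiff(colnames(df), "probe_id")), drop = FALSE]
}

#' @describeIn ColitisCohort-class sample ids of the normal (control) biopsies
#' @export
controlSamples <- function(x) {
  stopifnot(methods::is(x, "ColitisCohort"))
  rownames(colData(x))[colData(x)$diagnosis == "control"]
}

setMethod("show", "ColitisCohort", function(object) {
  cd <- colData(object)
  cat("ColitisCohort:", nrow(object), "probe sets x", ncol(object), "biopsies\n")
  cat("  diagnosis:", paste(sprintf("%s=%d", names(table(cd$diagnosis)),
                                    as.integer(table(cd$diagnosis))), collapse = ", "), "\n")
  em <- cd$endoscopic_mayo[!is.na(cd$endoscopic_mayo)]
  if (length(em)) {
    cat("  endoscopic Mayo:", paste(sprintf("%d=%d", 0:3,
                                            as.integer(table(factor(em, 0:3)))), collapse = ", "), "\n")
  }
  if (!is.null(metadata(object)$truth)) {
    cat("  planted truth: ", length(metadata(object)$truth$signal_probesets),
        " signal probe sets\n", sep = "")
  }
  invisible(object)
})

#' ActivityClasses: binary endoscopic activity labels
#'
#' Holds the active / inactive class of each included biopsy (active =
#' endoscopic Mayo subscore > 1), plus the cohort tag (`Mayo_Prob_1` for
#' UC-only, `Mayo_Prob_2` for UC + IBDU). Controls are never included.
#'
#' @slot labels named factor with levels `inactive`, `active`; names are
#'   sample ids.
#' @slot tag cohort tag.
#' @export
setClass("ActivityClasses",
         representation(labels = "factor", tag = "character"))

setValidity("ActivityClasses", function(object) {
  if (!identical(levels(object@labels), c("inactive", "active"))) {
    return("labels must be a factor with levels inactive, active")
  }
  if (is.null(names(object@labels)) || anyDuplicated(names(object@labels))) {
    return("labels must be uniquely named by sample id")
  }
  TRUE
})

#' @describeIn ActivityClasses-class named factor of class labels
#' @param x an `ActivityClasses`
#' @export
classLabels <- function(x) {
  stopifnot(methods::is(x, "ActivityClasses"))
  x@labels
}

#' @describeIn ActivityClasses-class ids of the included samples
#' @export
includedSamples <- function(x) {
  stopifnot(methods::is(x, "ActivityClasses"))
  names(x@labels)
}

#' @describeIn ActivityClasses-class cohort tag (`Mayo_Prob_1` / `Mayo_Prob_2`)
#' @export
cohortTag <- function(x) {
  stopifnot(methods::is(x, "ActivityClasses"))
  x@tag
}

setMethod("show", "ActivityClasses", function(object) {
  tab <- table(object@labels)
  cat("ActivityClasses [", object@tag, "]: ", sum(tab), " biopsies (",
      tab[["active"]], " active, ", tab[["inactive"]], " inactive)\n", sep = "")
  invisible(object)
})

#' CrossValidationResult: out-of-fold ensemble scores
#'
#' Result of [crossValidate()]: one out-of-fold score per sample per learner,
#' the median-ensemble score, the per-fold top-20 probe lists, and the pooled
#' Mann-Whitney AUC.
#'
#' @slot scores data.frame with `sample_id`, `fold`, `class`, one column per
#'   learner, and `ensemble`.
#' @slot features list of per-fold selected probe-id vectors.
#' @slot auc pooled out-of-fold AUC of the ensemble score.
#' @slot seed integer seed used for fold assignment and learners.
#' @slot tag cohort tag.
#' @slot learners learner names in roster order.
#' @export
setClass("CrossValidationResult",
         representation(scores = "data.frame", features = "list",
                        auc = "numeric", seed = "integer", tag = "character",
                        learners = "character"))

setValidity("CrossValidationResult", function(object) {
  sc <- object@scores
  need <- c("sample_id", "fold", "class", "ensemble")
  if (!all(need %in% colnames(sc))) {
    return(paste0("scores must contain ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(sc$sample_id)) return("each sample must be scored exactly once")
  if (any(sc$ensemble < 0 | sc$ensemble > 1)) return("ensemble scores must lie in [0, 1]")
  TRUE
})

#' @describeIn CrossValidationResult-class out-of-fold score table
#' @param x a `CrossValidationResult`
#' @export
cvScores <- function(x) {
  stopifnot(methods::is(x, "CrossValidationResult"))
  x@scores
}

#' @describeIn CrossValidationResult-class per-fold selected probe lists
#' @export
cvFeatures <- function(x) {
  stopifnot(methods::is(x, "CrossValidationResult"))
  x@features
}

#' @describeIn CrossValidationResult-class pooled out-of-fold ensemble AUC
#' @export
cvAUC <- function(x) {
  stopifnot(methods::is(x, "CrossValidationResult"))
  x@auc
}

setMethod("show", "CrossValidationResult", function(object) {
  cat("CrossValidationResult [", object@tag, "]: ", nrow(object@scores),
      " biopsies, ", length(object@features), " folds, ",
      length(object@learners), " learners\n", sep = "")
  cat("  pooled out-of-fold ensemble AUC:", sprintf("%.3f", object@auc), "\n")
  invisible(object)
})

#' ClassifierModel: refit ensemble for scoring new biopsies
#'
#' Produced by [fitFinalClassifier()]: the top-20 feature list selected on all
#' included samples and the fitted 12-learner panel.
#'
#' @slot features selected probe ids (length 20 by default).
#' @slot panel fitted learner panel (internal structure).
#' @slot tag training-cohort tag.
#' @slot seed integer seed used for learner fitting.
#' @export
setClass("ClassifierModel",
         representation(features = "character", panel = "list",
                        tag = "character", seed = "integer"))

setMethod("show", "ClassifierModel", function(object) {
  cat("ClassifierModel [", object@tag, "]: ", length(object@features),
      " features, ", length(object@panel$fits), " learners\n", sep = "")
  invisible(object)
})
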