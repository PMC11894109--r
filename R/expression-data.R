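#' Load a cohort from expression, sample, and annotation files
#'
#' Reads a probe-set x sample log2 expression TSV (first column `probe_id`,
#' remaining columns sample ids), a clinical sample CSV, and a probe
#' annotation CSV, validates cross-file id consistency, and returns a
#' [ColitisCohort-class]. If a `truth.json` sidecar sits next to the matrix
#' (written by [writeCohortFiles()]), the planted truth is re-attached.
#'
#' Validation is strict: duplicated ids, samples missing from either file,
#' or non-finite expression values fail hard, naming the offending ids. A
#' short load report (counts per diagnosis and Mayo subscore) is emitted as a
#' message.
#'
#' @param matrix_path path to the expression TSV.
#' @param samples_path path to the clinical sample CSV.
#' @param annotation_path path to the probe annotation CSV
#'   (`probe_id,gene_symbol,flags`).
#' @return A validated `ColitisCohort`.
#' @export
loadCohort <- function(matrix_path, samples_path, annotation_path) {
  for (f in c(matrix_path, samples_path, annotation_path)) {
    .stopIfNot(file.exists(f), "loadCohort: file not found: ", f)
  }
  mat_df <- utils::read.delim(matrix_path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  .stopIfNot(colnames(mat_df)[1] == "probe_id",
             "loadCohort: first matrix column must be probe_id")
  probe_ids <- as.character(mat_df$probe_id)
  if (anyDuplicated(probe_ids)) {
    stop("loadCohort: duplicated probe ids in matrix: ",
         paste(utils::head(unique(probe_ids[duplicated(probe_ids)]), 5), collapse = ", "))
  }
  x <- as.matrix(mat_df[, -1, drop = FALSE])
  mode(x) <- "numeric"
  rownames(x) <- probe_ids
  if (anyDuplicated(colnames(x))) {
    stop("loadCohort: duplicated sample ids in matrix: ",
         paste(utils::head(unique(colnames(x)[duplicated(colnames(x))]), 5), collapse = ", "))
  }
  if (anyNA(x) || !all(is.finite(x))) {
    bad <- colnames(x)[colSums(!is.finite(x)) > 0]
    stop("loadCohort: non-finite expression values in sample(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  .stopIfNot("sample_id" %in% colnames(samples),
             "loadCohort: sample table requires a sample_id column")
  if (anyDuplicated(samples$sample_id)) {
    stop("loadCohort: duplicated sample ids in sample table: ",
         paste(utils::head(unique(samples$sample_id[duplicated(samples$sample_id)]), 5),
               collapse = ", "))
  }
  annotation <- utils::read.csv(annotation_path, stringsAsFactors = FALSE)
  cohort <- ColitisCohort(x, samples, annotation)

  sidecar <- file.path(dirname(matrix_path), "truth.json")
  if (file.exists(sidecar)) {
    metadata(cohort)$truth <- cohortTruth(dirname(matrix_path))
  }

  cd <- sampleInfo(cohort)
  em <- cd$endoscopic_mayo[!is.na(cd$endoscopic_mayo)]
  message("loadCohort: ", nrow(cohort), " probe sets x ", ncol(cohort), " samples; ",
          paste(sprintf("%s=%d", names(table(cd$diagnosis)),
                        as.integer(table(cd$diagnosis))), collapse = ", "),
          "; Mayo ", paste(sprintf("%d:%d", 0:3,
                                   as.integer(table(factor(em, 0:3)))), collapse = " "))
  cohort
}

#' Harmonize labeling-kit batches by per-probe mean matching
#'
#' The two labeling kits introduce probe-specific intensity offsets. This
#' correction applies, per probe, an additive log2 offset to the non-reference
#' kit so that the per-kit probe means coincide (equivalent to a
#' multiplicative correction factor on the linear scale). The reference kit is
#' the kit with more samples (ties favor `kit_A`). With all samples in one kit
#' the matrix is returned unchanged. The correction is idempotent and leaves
#' all within-kit contrasts untouched; note that any kit-class confounding is
#' not adjusted, only the marginal batch offset.
#'
#' @param cohort a `ColitisCohort` (its `labeling_kit` column drives the
#'   correction).
#' @return The cohort with corrected `exprs` assay.
#' @export
applyKitCorrection <- function(cohort) {
  .stopIfNot(methods::is(cohort, "ColitisCohort"), "applyKitCorrection: not a ColitisCohort")
  kit <- sampleInfo(cohort)$labeling_kit
  tab <- table(kit)
  if (length(tab) < 2L) return(cohort)
  .stopIfNot(all(tab >= 2L),
             "applyKitCorrection: each kit needs >= 2 samples (got ",
             paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
             "); offset would be degenerate")
  ref <- if (tab[["kit_A"]] >= tab[["kit_B"]]) "kit_A" else "kit_B"
  other <- setdiff(names(tab), ref)
  x <- exprsMatrix(cohort)
  offset <- rowMeans(x[, kit == other, drop = FALSE]) -
    rowMeans(x[, kit == ref, drop = FALSE])
  x[, kit == other] <- x[, kit == other] - offset
  assay(cohort, "exprs") <- x
  cohort
}

#' Define the binary endoscopic activity classes
#'
#' Active disease is endoscopic Mayo subscore > 1; inactive is <= 1. Controls
#' are never included. With `include_ibdu = FALSE` only UC biopsies enter
#' (the `Mayo_Prob_1` training cohort); with `include_ibdu = TRUE` UC and
#' IBDU biopsies enter (`Mayo_Prob_2`).
#'
#' @param cohort a `ColitisCohort` (or its sample `data.frame`).
#' @param include_ibdu include IBDU biopsies?
#' @return An [ActivityClasses-class] object.
#' @export
defineActivityClasses <- function(cohort, include_ibdu = FALSE) {
  samples <- if (methods::is(cohort, "ColitisCohort")) sampleInfo(cohort) else as.data.frame(cohort)
  keep_dx <- if (include_ibdu) c("UC", "IBDU") else "UC"
  keep <- samples$diagnosis %in% keep_dx
  ids <- rownames(samples)[keep]
  mayo <- samples$endoscopic_mayo[keep]
  .stopIfNot(!anyNA(mayo), "defineActivityClasses: included sample(s) without endoscopic_mayo: ",
             paste(utils::head(ids[is.na(mayo)], 5), collapse = ", "))
  lab <- factor(ifelse(mayo > 1, "active", "inactive"),
                levels = c("inactive", "active"))
  names(lab) <- ids
  tab <- table(lab)
  if (any(tab == 0L)) {
    stop("defineActivityClasses: class '", names(tab)[tab == 0L][1],
         "' is empty; classifier untrainable")
  }
  methods::new("ActivityClasses", labels = lab,
               tag = if (include_ibdu) "Mayo_Prob_2" else "Mayo_Prob_1")
}
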