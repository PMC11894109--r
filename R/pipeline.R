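#' Run the full molecular-scoring pipeline
#'
#' Orchestrates every stage with one config and one seed family:
#' load-or-simulate the cohort, labeling-kit correction, activity classes,
#' moderated-t differential expression (volcano and top lists), the two
#' cross-validated ensemble classifiers (`Mayo_Prob_1` UC-only,
#' `Mayo_Prob_2` UC + IBDU), the MCalpro transcript-set score,
#' overrepresentation analysis (when a GMT is supplied), and the
#' outcome-association battery. All stage outputs are written as CSV under
#' `out_dir` together with `report.json` (key numbers: per-cohort AUC,
#' correlation table, LRT p-values, importance ranking, config echo). Outputs
#' contain no timestamps, so identical config + seed reruns are byte-identical.
#'
#' @param config a list with elements:
#'   * exactly one of `simulate` (arguments for [cohortConfig()]) or `paths`
#'     (list with `matrix`, `samples`, `annotation` file paths);
#'   * `out_dir` output directory;
#'   * optional `seed` (default 1), `k` folds (default 10), `n_features`
#'     (default 20), `top_n` enrichment list size (default 150), `gmt` path,
#'     `kit_correction` (default `TRUE`).
#' @return Invisibly, the report list.
#' @export
runPipeline <- function(config) {
  .stopIfNot(is.list(config), "runPipeline: config must be a list")
  .stopIfNot(xor(!is.null(config$simulate), !is.null(config$paths)),
             "runPipeline: exactly one of config$simulate / config$paths required")
  .stopIfNot(!is.null(config$out_dir), "runPipeline: config$out_dir required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  k <- if (is.null(config$k)) 10L else as.integer(config$k)
  n_features <- if (is.null(config$n_features)) 20L else as.integer(config$n_features)
  top_n <- if (is.null(config$top_n)) 150L else as.integer(config$top_n)
  kit_correction <- if (is.null(config$kit_correction)) TRUE else isTRUE(config$kit_correction)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }

  # --- cohort -------------------------------------------------------------
  cohort <- stage("cohort", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      if (is.null(sim$seed)) sim$seed <- seed
      do.call(cohortConfig, sim) |> simulateCohort()
    } else {
      loadCohort(config$paths$matrix, config$paths$samples, config$paths$annotation)
    }
  })
  if (kit_correction && length(unique(sampleInfo(cohort)$labeling_kit)) > 1L) {
    cohort <- stage("kit_correction", applyKitCorrection(cohort))
  }

  # --- classes + differential expression ---------------------------------
  has_ibdu <- any(sampleInfo(cohort)$diagnosis == "IBDU")
  classes1 <- stage("classes", defineActivityClasses(cohort, include_ibdu = FALSE))
  classes2 <- if (has_ibdu) {
    stage("classes", defineActivityClasses(cohort, include_ibdu = TRUE))
  } else NULL

  de <- stage("differential_expression", fitModeratedT(cohort, classes1))
  wcsv(de, "de_table.csv")
  wcsv(volcanoTable(de, cohort), "volcano.csv")
  wcsv(rankTranscripts(de, "increased", k = 30, collapse_to_genes = TRUE),
       "top_increased.csv")
  wcsv(rankTranscripts(de, "decreased", k = 30, collapse_to_genes = TRUE),
       "top_decreased.csv")

  # --- classifiers --------------------------------------------------------
  cv1 <- stage("classifier_Mayo_Prob_1",
               crossValidate(cohort, classes1, k = k, seed = seed,
                             n_features = n_features))
  wcsv(cvScores(cv1), "cv_scores_Mayo_Prob_1.csv")
  wcsv(.featureTable(cv1), "cv_features_Mayo_Prob_1.csv")
  cv2 <- NULL
  if (!is.null(classes2)) {
    cv2 <- stage("classifier_Mayo_Prob_2",
                 crossValidate(cohort, classes2, k = k, seed = seed,
                               n_features = n_features))
    wcsv(cvScores(cv2), "cv_scores_Mayo_Prob_2.csv")
    wcsv(.featureTable(cv2), "cv_features_Mayo_Prob_2.csv")
  }

  # --- transcript-set score ----------------------------------------------
  mcal <- stage("set_scores", mcalproScore(cohort))
  wcsv(data.frame(sample_id = names(mcal), mcalpro = unname(mcal),
                  stringsAsFactors = FALSE), "set_scores.csv")

  # --- enrichment ---------------------------------------------------------
  enr <- NULL
  if (!is.null(config$gmt)) {
    enr <- stage("enrichment", {
      universe <- unique(probeInfo(cohort)$gene_symbol)
      universe <- universe[!is.na(universe) & universe != ""]
      genes <- selectEnrichmentInput(de, n = top_n)
      oraTest(genes, readGeneSets(config$gmt), universe = universe)
    })
    wcsv(enr, "enrichment.csv")
  }

  # --- outcome battery ----------------------------------------------------
  pred <- stage("outcomes", buildPredictorTable(cohort, cv1, cv2, mcal))
  wcsv(pred, "predictor_table.csv")

  corr <- stage("outcomes", {
    mol <- c("mayo_prob_1", if (!is.null(cv2)) "mayo_prob_2", "mcalpro")
    clin <- c("total_mayo", "partial_mayo", "pga", "endoscopic_mayo",
              "fecal_calprotectin")
    do.call(rbind, lapply(mol, function(m) {
      do.call(rbind, lapply(clin, function(cl) {
        res <- tryCatch(spearmanTest(pred[[m]], pred[[cl]]),
                        error = function(e) list(rho = NA_real_, p = NA_real_,
                                                 n = NA_integer_, undefined = TRUE))
        data.frame(score = m, clinical = cl, rho = res$rho, p = res$p,
                   n = res$n, stringsAsFactors = FALSE)
      }))
    }))
  })
  wcsv(corr, "correlations.csv")

  grp <- stage("outcomes", {
    vars <- c("total_mayo", "pga", "partial_mayo", "endoscopic_mayo",
              "fecal_calprotectin", "mayo_prob_1",
              if (!is.null(cv2)) "mayo_prob_2", "mcalpro")
    do.call(rbind, lapply(vars, function(v) {
      ok <- !is.na(pred$poor_outcome) & is.finite(pred[[v]])
      good <- pred[[v]][ok & pred$poor_outcome == 0L]
      poor <- pred[[v]][ok & pred$poor_outcome == 1L]
      res <- tryCatch(welchTest(good, poor),
                      error = function(e) list(t = NA_real_, df = NA_real_,
                                               p = NA_real_,
                                               mean_a = mean(good), mean_b = mean(poor),
                                               n_a = length(good), n_b = length(poor)))
      data.frame(variable = v, mean_good = res$mean_a, mean_poor = res$mean_b,
                 n_good = res$n_a, n_poor = res$n_b, t = res$t, p = res$p,
                 stringsAsFactors = FALSE)
    }))
  })
  wcsv(grp, "group_tests.csv")

  screen <- stage("outcomes", singlePredictorScreen(pred))
  mol_vars <- c("mayo_prob_1", if (!is.null(cv2)) "mayo_prob_2", "mcalpro")
  clin_vars <- c("endoscopic_mayo", "total_mayo", "fecal_calprotectin")
  lrt_mol <- stage("outcomes", tryCatch(
    likelihoodRatioCompare(pred, clin_vars, c(clin_vars, mol_vars)),
    error = function(e) NULL))
  lrt_clin <- stage("outcomes", tryCatch(
    likelihoodRatioCompare(pred, mol_vars, c(clin_vars, mol_vars)),
    error = function(e) NULL))
  comp <- rbind(
    data.frame(comparison = "molecular_add_to_clinical",
               reduced = paste(clin_vars, collapse = "+"),
               full = paste(c(clin_vars, mol_vars), collapse = "+"),
               lrt = if (is.null(lrt_mol)) NA_real_ else lrt_mol$lrt,
               df = if (is.null(lrt_mol)) NA_integer_ else lrt_mol$df,
               p = if (is.null(lrt_mol)) NA_real_ else lrt_mol$p,
               n = if (is.null(lrt_mol)) NA_integer_ else lrt_mol$n,
               stringsAsFactors = FALSE),
    data.frame(comparison = "clinical_add_to_molecular",
               reduced = paste(mol_vars, collapse = "+"),
               full = paste(c(clin_vars, mol_vars), collapse = "+"),
               lrt = if (is.null(lrt_clin)) NA_real_ else lrt_clin$lrt,
               df = if (is.null(lrt_clin)) NA_integer_ else lrt_clin$df,
               p = if (is.null(lrt_clin)) NA_real_ else lrt_clin$p,
               n = if (is.null(lrt_clin)) NA_integer_ else lrt_clin$n,
               stringsAsFactors = FALSE)
  )
  wcsv(cbind(screen, stringsAsFactors = FALSE), "single_predictor_screen.csv")
  wcsv(comp, "model_comparison.csv")

  imp <- stage("outcomes", tryCatch(
    permutationImportance(pred, seed = seed),
    error = function(e) NULL))
  if (!is.null(imp)) wcsv(imp, "importance.csv")

  report <- list(
    seed = seed, k = k, n_features = n_features,
    n_samples = ncol(cohort), n_probesets = nrow(cohort),
    auc = list(Mayo_Prob_1 = cvAUC(cv1),
               Mayo_Prob_2 = if (!is.null(cv2)) cvAUC(cv2) else NA_real_),
    n_fdr_significant = sum(de$p_fdr < 0.05),
    correlations = corr,
    lrt = list(molecular_add_to_clinical = if (is.null(lrt_mol)) NULL else lrt_mol$p,
               clinical_add_to_molecular = if (is.null(lrt_clin)) NULL else lrt_clin$p),
    importance = if (is.null(imp)) NULL else imp,
    config = config[setdiff(names(config), "out_dir")]
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

.featureTable <- function(cv) {
  feats <- cvFeatures(cv)
  do.call(rbind, lapply(seq_along(feats), function(f) {
    data.frame(fold = f, rank = seq_along(feats[[f]]), probe_id = feats[[f]],
               stringsAsFactors = FALSE)
  }))
}
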