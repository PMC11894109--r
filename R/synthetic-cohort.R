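#' Configuration for the synthetic microarray cohort generator
#'
#' Defines the study conditions the simulator emulates: a prospective UC/IBDU
#' biopsy cohort with normal-colon controls profiled on a ~49,495 probe-set
#' array, an activity-dependent transcriptional signal planted in a subset of
#' probe sets, calprotectin transcripts (S100A8/S100A9) coupled to activity
#' and to a noisy fecal calprotectin measurement, two labeling-kit batches,
#' and 3-6-month status codes driven by latent molecular severity.
#'
#' Defaults mirror the emulated study: 128 UC + 13 IBDU biopsies, 17 controls,
#' 49,495 probe sets, and endoscopic Mayo subscore weights taken from the
#' cohort's printed distribution. Sizes are scaled down in tests.
#'
#' @param n_uc_biopsies,n_ibdu_biopsies,n_controls sample counts per group.
#' @param n_probesets number of probe sets on the simulated array.
#' @param n_signal_probesets number of probe sets carrying a planted
#'   activity effect (must be >= 2: the S100A8/S100A9 pair is always planted).
#' @param effect_size planted shift in log2 units per unit of latent severity;
#'   per-probe magnitudes are drawn as `effect_size * U(0.5, 1.5)` with random
#'   sign (S100A8/A9 get `+2 * effect_size`).
#' @param mayo_distribution probability weights over endoscopic Mayo
#'   subscores 0-3 (must sum to 1).
#' @param kit_fraction fraction of samples labeled with the second kit.
#' @param kit_offset_sd SD (log2 units) of the per-probe additive batch
#'   offset applied to second-kit samples.
#' @param noise_sd typical residual SD in log2 units; per-probe SDs vary
#'   lognormally around it.
#' @param calprotectin_noise_sd SD (natural-log units) of the lognormal noise
#'   on fecal calprotectin.
#' @param endoscopy_error_sd SD of the gap between latent molecular severity
#'   and the endoscopic severity implied by the Mayo subscore (endoscopy
#'   grades tissue inflammation with error).
#' @param calprotectin_fraction fraction of diseased biopsies with an observed
#'   fecal calprotectin value.
#' @param status_fraction fraction of diseased biopsies with 3-6-month
#'   follow-up (and hence a status code).
#' @param confound_kit_with_activity if `TRUE`, kit assignment probability
#'   increases with severity (for batch-confounding sensitivity checks);
#'   default `FALSE` keeps kit independent of severity.
#' @param seed integer RNG seed; generation is fully reproducible.
#' @return A validated `cohort_config` list.
#' @export
cohortConfig <- function(n_uc_biopsies = 128L,
                         n_ibdu_biopsies = 13L,
                         n_controls = 17L,
                         n_probesets = 49495L,
                         n_signal_probesets = 200L,
                         effect_size = 1.0,
                         mayo_distribution = c(25, 33, 49, 34) / 141,
                         kit_fraction = 0.5,
                         kit_offset_sd = 0.25,
                         noise_sd = 1.0,
                         calprotectin_noise_sd = 1.8,
                         endoscopy_error_sd = 0.6,
                         calprotectin_fraction = 0.6,
                         status_fraction = 80 / 141,
                         confound_kit_with_activity = FALSE,
                         seed = 1L) {
  cfg <- list(
    n_uc_biopsies = as.integer(n_uc_biopsies),
    n_ibdu_biopsies = as.integer(n_ibdu_biopsies),
    n_controls = as.integer(n_controls),
    n_probesets = as.integer(n_probesets),
    n_signal_probesets = as.integer(n_signal_probesets),
    effect_size = as.numeric(effect_size),
    mayo_distribution = as.numeric(mayo_distribution),
    kit_fraction = as.numeric(kit_fraction),
    kit_offset_sd = as.numeric(kit_offset_sd),
    noise_sd = as.numeric(noise_sd),
    calprotectin_noise_sd = as.numeric(calprotectin_noise_sd),
    endoscopy_error_sd = as.numeric(endoscopy_error_sd),
    calprotectin_fraction = as.numeric(calprotectin_fraction),
    status_fraction = as.numeric(status_fraction),
    confound_kit_with_activity = isTRUE(confound_kit_with_activity),
    seed = as.integer(seed)
  )
  counts <- c("n_uc_biopsies", "n_ibdu_biopsies", "n_controls",
              "n_probesets", "n_signal_probesets")
  for (f in counts) {
    .stopIfNot(!is.na(cfg[[f]]) && cfg[[f]] >= 0L, "cohortConfig: ", f, " must be >= 0")
  }
  .stopIfNot(cfg$n_signal_probesets <= cfg$n_probesets,
             "cohortConfig: n_signal_probesets must not exceed n_probesets")
  .stopIfNot(cfg$n_signal_probesets >= 2L,
             "cohortConfig: n_signal_probesets must be >= 2 (the S100A8/S100A9 pair must exist)")
  .stopIfNot(length(cfg$mayo_distribution) == 4L &&
               all(cfg$mayo_distribution >= 0) &&
               abs(sum(cfg$mayo_distribution) - 1) <= 1e-9,
             "cohortConfig: mayo_distribution must be 4 non-negative weights summing to 1")
  .stopIfNot(cfg$kit_fraction >= 0 && cfg$kit_fraction <= 1,
             "cohortConfig: kit_fraction must be in [0, 1]")
  .stopIfNot(cfg$noise_sd > 0, "cohortConfig: noise_sd must be > 0")
  class(cfg) <- "cohort_config"
  cfg
}

# probes-per-gene ratio of the emulated array (49,495 probe sets for
# 19,462 unique transcripts).
.PROBES_PER_GENE <- 49495 / 19462

#' Generate a seeded synthetic biopsy cohort with planted ground truth
#'
#' Draws a log2 expression matrix with per-probe baseline mean/SD, plants an
#' activity-coupled shift (`effect * molecular severity`) in
#' `n_signal_probesets` probe sets, couples two designated S100A8/S100A9
#' probe sets to activity and to a noisy lognormal fecal calprotectin value,
#' adds per-probe labeling-kit offsets to second-kit samples, and assigns
#' 3-6-month status codes whose probability of a poor outcome
#' (`status > 1`) is an increasing logistic function of molecular severity.
#' Controls carry zero severity and no Mayo grading.
#'
#' Severity structure: each diseased biopsy's endoscopic severity is its Mayo
#' subscore plus `U(-0.25, 0.25)` jitter; its latent *molecular* severity adds
#' `N(0, endoscopy_error_sd)` on top, reflecting that endoscopy grades tissue
#' inflammation with error. Expression, calprotectin and status are driven by
#' molecular severity.
#'
#' @param config a [cohortConfig()] list.
#' @return A [ColitisCohort-class] whose `metadata(x)$truth` holds the planted
#'   truth: `signal_probesets`, per-probe `planted_effect`, per-sample
#'   `severity` (molecular) and `endoscopic_severity`, per-probe
#'   `kit_offsets`, `baseline_mean`, the `s100_probesets`, and a config echo.
#' @export
simulateCohort <- function(config = cohortConfig()) {
  .stopIfNot(inherits(config, "cohort_config"),
             "simulateCohort: config must come from cohortConfig()")
  .withSeed(config$seed, {
    p <- config$n_probesets
    n_uc <- config$n_uc_biopsies
    n_ibdu <- config$n_ibdu_biopsies
    n_ctl <- config$n_controls
    n_dis <- n_uc + n_ibdu
    n <- n_dis + n_ctl
    .stopIfNot(n_dis > 0, "simulateCohort: at least one diseased biopsy required")

    probe_ids <- sprintf("PS%06d_at", seq_len(p))
    sample_ids <- c(sprintf("UC%03d", seq_len(n_uc)),
                    sprintf("IBDU%03d", seq_len(n_ibdu)),
                    sprintf("CTRL%03d", seq_len(n_ctl)))
    diagnosis <- c(rep("UC", n_uc), rep("IBDU", n_ibdu), rep("control", n_ctl))
    is_ctl <- diagnosis == "control"

    # --- probe-level parameters -------------------------------------------
    baseline_mean <- stats::rnorm(p, mean = 7, sd = 1.5)
    probe_sd <- config$noise_sd * exp(stats::rnorm(p, 0, 0.25))
    signal_idx <- sort(sample.int(p, config$n_signal_probesets))
    s100_idx <- signal_idx[sample.int(length(signal_idx), 2L)]
    effect <- numeric(p)
    effect[signal_idx] <- config$effect_size * stats::runif(length(signal_idx), 0.5, 1.5) *
      sample(c(-1, 1), length(signal_idx), replace = TRUE)
    # calprotectin pair: always increased with activity, and measured with low
    # noise (S100A8/A9 are abundant, direct readouts of neutrophil influx);
    # the 0.8 coupling keeps MCalpro on the few-fold-over-control scale
    effect[s100_idx] <- 0.8 * config$effect_size
    probe_sd[s100_idx] <- 0.35
    kit_offsets <- stats::rnorm(p, 0, config$kit_offset_sd)

    # --- sample-level parameters ------------------------------------------
    mayo <- rep(NA_integer_, n)
    mayo[!is_ctl] <- sample(0:3, n_dis, replace = TRUE, prob = config$mayo_distribution)
    endo_sev <- numeric(n)
    endo_sev[!is_ctl] <- mayo[!is_ctl] + stats::runif(n_dis, -0.25, 0.25)
    mol_sev <- numeric(n)
    mol_sev[!is_ctl] <- endo_sev[!is_ctl] + stats::rnorm(n_dis, 0, config$endoscopy_error_sd)

    pga <- rep(NA_integer_, n)
    pga[!is_ctl] <- pmin(3L, pmax(0L, as.integer(round(endo_sev[!is_ctl] * 0.9 +
                                                         stats::rnorm(n_dis, 0, 0.4)))))
    partial <- rep(NA_integer_, n)
    partial[!is_ctl] <- pmin(9L, pmax(0L, as.integer(round(endo_sev[!is_ctl] * 2.2 +
                                                             stats::rnorm(n_dis, 0, 1)))))
    total <- rep(NA_integer_, n)
    total[!is_ctl] <- partial[!is_ctl] + mayo[!is_ctl]

    if (config$confound_kit_with_activity) {
      pr_b <- stats::plogis(stats::qlogis(pmin(pmax(config$kit_fraction, 1e-6), 1 - 1e-6)) +
                              0.8 * (mol_sev - mean(mol_sev)))
      kit <- ifelse(stats::runif(n) < pr_b, "kit_B", "kit_A")
    } else {
      kit <- ifelse(stats::runif(n) < config$kit_fraction, "kit_B", "kit_A")
    }

    center <- sample(c("center_1", "center_2"), n, replace = TRUE, prob = c(0.8, 0.2))
    patient <- sprintf("P%03d", seq_len(n))  # biopsies independent by design

    # --- expression matrix ------------------------------------------------
    x <- matrix(stats::rnorm(p * n, sd = probe_sd), nrow = p, ncol = n)
    x <- x + baseline_mean
    if (length(signal_idx)) {
      x[signal_idx, ] <- x[signal_idx, ] +
        outer(effect[signal_idx], mol_sev)
    }
    kit_b <- kit == "kit_B"
    if (any(kit_b)) x[, kit_b] <- x[, kit_b] + kit_offsets
    dimnames(x) <- list(probe_ids, sample_ids)

    # --- fecal calprotectin: lognormal, coupled to tissue S100A8/A9 -------
    s100_expr <- colMeans(x[s100_idx, , drop = FALSE])
    s100_base <- mean(baseline_mean[s100_idx])
    fcal <- rep(NA_real_, n)
    obs <- !is_ctl & stats::runif(n) < config$calprotectin_fraction
    fcal[obs] <- exp(log(60) + 1.6 * (s100_expr[obs] - s100_base) +
                       stats::rnorm(sum(obs), 0, config$calprotectin_noise_sd))

    # --- 3-6-month status code driven by molecular severity ---------------
    status <- rep(NA_integer_, n)
    fu <- !is_ctl & stats::runif(n) < config$status_fraction
    if (any(fu)) {
      poor <- stats::runif(sum(fu)) < stats::plogis(-2.2 + 1.3 * mol_sev[fu])
      status[fu] <- ifelse(poor,
                           sample(2:3, sum(fu), replace = TRUE),
                           sample(0:1, sum(fu), replace = TRUE))
    }

    samples <- data.frame(
      sample_id = sample_ids,
      patient_id = patient,
      diagnosis = diagnosis,
      endoscopic_mayo = mayo,
      partial_mayo = partial,
      total_mayo = total,
      pga = pga,
      fecal_calprotectin = fcal,
      labeling_kit = kit,
      center = center,
      status_code = status,
      stringsAsFactors = FALSE
    )

    # --- probe annotation: several probe sets per gene, S100A8/A9 named ---
    n_genes <- max(1L, as.integer(ceiling(p / .PROBES_PER_GENE)))
    gene_of <- sprintf("GENE%05d", ((seq_len(p) - 1L) %% n_genes) + 1L)
    gene_of[s100_idx] <- c("S100A8", "S100A9")
    flags <- rep("", p)
    flags[s100_idx] <- "calprotectin"
    pool <- setdiff(seq_len(p), s100_idx)
    if (length(pool) >= 40) {
      flag_pick <- sample(pool, 40)
      flags[flag_pick[1:20]] <- "therapy-target"
      flags[flag_pick[21:30]] <- "inflammasome"
      flags[flag_pick[31:40]] <- "solute-carrier"
    }
    annotation <- data.frame(probe_id = probe_ids, gene_symbol = gene_of,
                             flags = flags, stringsAsFactors = FALSE)

    truth <- list(
      signal_probesets = probe_ids[signal_idx],
      planted_effect = stats::setNames(effect, probe_ids),
      severity = stats::setNames(mol_sev, sample_ids),
      endoscopic_severity = stats::setNames(endo_sev, sample_ids),
      kit_offsets = stats::setNames(kit_offsets, probe_ids),
      baseline_mean = stats::setNames(baseline_mean, probe_ids),
      s100_probesets = stats::setNames(probe_ids[s100_idx], c("S100A8", "S100A9")),
      config = unclass(config)
    )
    ColitisCohort(x, samples, annotation, truth = truth)
  })
}

#' Retrieve the planted ground truth of a synthetic cohort
#'
#' For an in-memory [simulateCohort()] result, returns the truth stored in its
#' metadata; for a directory written by [writeCohortFiles()], reads the
#' `truth.json` sidecar.
#'
#' @param x a `ColitisCohort` or the path of a cohort directory.
#' @return The truth list (see [simulateCohort()]).
#' @export
cohortTruth <- function(x) {
  if (methods::is(x, "ColitisCohort")) {
    tr <- metadata(x)$truth
    if (is.null(tr)) stop("no truth available: cohort was not produced by simulateCohort()")
    return(tr)
  }
  if (is.character(x) && length(x) == 1L) {
    path <- file.path(x, "truth.json")
    if (!file.exists(path)) stop("no truth available: missing sidecar ", path)
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (f in c("planted_effect", "severity", "endoscopic_severity",
                "kit_offsets", "baseline_mean", "s100_probesets")) {
      raw[[f]] <- unlist(raw[[f]])
    }
    return(raw)
  }
  stop("cohortTruth: x must be a ColitisCohort or a cohort directory path")
}

#' Write a cohort to plain-text files (with a truth sidecar)
#'
#' Writes `matrix.tsv` (probe rows, first column `probe_id`, one column per
#' sample), `samples.csv`, `annotation.csv`, and — when planted truth is
#' present — a `truth.json` sidecar.
#'
#' @param cohort a `ColitisCohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeCohortFiles <- function(cohort, dir) {
  .stopIfNot(methods::is(cohort, "ColitisCohort"), "writeCohortFiles: not a ColitisCohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  x <- exprsMatrix(cohort)
  mat_path <- file.path(dir, "matrix.tsv")
  mat_df <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                       stringsAsFactors = FALSE)
  utils::write.table(mat_df, mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  samp <- sampleInfo(cohort)
  samp <- data.frame(sample_id = rownames(samp), samp, check.names = FALSE,
                     stringsAsFactors = FALSE)
  samp_path <- file.path(dir, "samples.csv")
  utils::write.csv(samp, samp_path, row.names = FALSE)
  ann_path <- file.path(dir, "annotation.csv")
  utils::write.csv(probeInfo(cohort), ann_path, row.names = FALSE)
  paths <- c(matrix = mat_path, samples = samp_path, annotation = ann_path)
  tr <- metadata(cohort)$truth
  if (!is.null(tr)) {
    truth_path <- file.path(dir, "truth.json")
    tr_json <- tr
    for (f in c("planted_effect", "severity", "endoscopic_severity",
                "kit_offsets", "baseline_mean", "s100_probesets")) {
      tr_json[[f]] <- as.list(tr[[f]])  # keep names in JSON
    }
    jsonlite::write_json(tr_json, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, truth = truth_path)
  }
  invisible(paths)
}
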