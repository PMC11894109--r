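# Shared fixtures, built once per test run and cached.

suppressMessages(library(SummarizedExperiment))  # assay<- in tests

.fixtures <- new.env()

# Mid-sized planted-signal cohort: enough power for precision/monotonicity
# checks while keeping unit tests fast.
plantedCohort <- function() {
  if (is.null(.fixtures$planted)) {
    cfg <- cohortConfig(n_uc_biopsies = 100, n_ibdu_biopsies = 10,
                        n_controls = 12, n_probesets = 1500,
                        n_signal_probesets = 80, effect_size = 1.0,
                        seed = 424L)
    .fixtures$planted <- simulateCohort(cfg)
  }
  .fixtures$planted
}

# Tiny cohort for structural/IO tests.
tinyCohort <- function() {
  if (is.null(.fixtures$tiny)) {
    cfg <- cohortConfig(n_uc_biopsies = 30, n_ibdu_biopsies = 4,
                        n_controls = 6, n_probesets = 120,
                        n_signal_probesets = 10, effect_size = 1.2,
                        seed = 99L)
    .fixtures$tiny <- simulateCohort(cfg)
  }
  .fixtures$tiny
}

# Deterministic hand-built expression matrix + classes (no simulator).
handMatrix <- function(n_probes = 50, n_per_class = 10, seed = 5L,
                       delta = 0) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n_probes * n, mean = 8), n_probes, n,
              dimnames = list(sprintf("P%03d", seq_len(n_probes)),
                              sprintf("S%02d", seq_len(n))))
  lab <- factor(rep(c("inactive", "active"), each = n_per_class),
                levels = c("inactive", "active"))
  names(lab) <- colnames(x)
  x[, lab == "active"] <- x[, lab == "active"] + delta
  list(x = x,
       classes = methods::new("ActivityClasses", labels = lab, tag = "Mayo_Prob_1"))
}

# Wrap a bare matrix as a ColitisCohort with a chosen labeling-kit vector
# (all-UC samples, cycling Mayo subscores).
.makeKitCohort <- function(x, kit) {
  n <- ncol(x)
  samples <- data.frame(
    sample_id = colnames(x),
    patient_id = paste0("p", seq_len(n)),
    diagnosis = "UC",
    endoscopic_mayo = rep(0:3, length.out = n),
    partial_mayo = rep(0:3, length.out = n) * 2L,
    total_mayo = rep(0:3, length.out = n) * 3L,
    pga = rep(0:3, length.out = n),
    fecal_calprotectin = NA_real_,
    labeling_kit = kit,
    center = "c1",
    status_code = NA_integer_,
    stringsAsFactors = FALSE
  )
  ann <- data.frame(probe_id = rownames(x), gene_symbol = rownames(x),
                    flags = "", stringsAsFactors = FALSE)
  ColitisCohort(x, samples, ann)
}

# Small GMT file written to a temp path.
writeTestGMT <- function(lines = c(
  "setA\tdescA\tG1\tG2\tG3",
  "setB\tdescB\tG2\tG4\tG5\tG6")) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}
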