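#' Read gene-set collections from a GMT file
#'
#' GMT format: one set per line, tab-separated `name`, `description`,
#' members. Lines with fewer than three fields fail with their line number;
#' duplicated set names fail. Members absent from the universe are dropped at
#' test time by intersection; sets that become empty are dropped with a
#' warning by [oraTest()].
#'
#' @param path GMT file path.
#' @param universe optional character vector of gene symbols; when `NULL`,
#'   the universe must be supplied to [oraTest()] (conventionally all genes
#'   represented on the array).
#' @return A list with `sets` (named list of character vectors) and
#'   `universe` (possibly `NULL`).
#' @export
readGeneSets <- function(path, universe = NULL) {
  .stopIfNot(file.exists(path), "readGeneSets: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  nfield <- vapply(strsplit(lines[nonblank], "\t", fixed = TRUE), length, integer(1))
  bad <- nonblank[nfield < 3L]
  .stopIfNot(length(bad) == 0L,
             "readGeneSets: malformed GMT line ", if (length(bad)) bad[1] else "",
             " (need name, description, members)")
  nm <- vapply(strsplit(lines[nonblank], "\t", fixed = TRUE), `[[`, character(1), 1L)
  dup <- unique(nm[duplicated(nm)])
  .stopIfNot(length(dup) == 0L, "readGeneSets: duplicated set name(s): ",
             paste(utils::head(dup, 5), collapse = ", "))
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, unique)
  list(sets = sets, universe = universe)
}

#' Select the enrichment input gene list
#'
#' The top `n` transcripts increased with activity (ranked by unadjusted p,
#' collapsed to unique gene symbols via each gene's best probe), mapped to
#' gene symbols. A warning is emitted if any selected transcript has
#' `p_fdr >= 0.05` (the intended usage is a list that is significant
#' genome-wide), or if fewer than `n` increased transcripts exist.
#'
#' @param de a `data.frame` from [fitModeratedT()].
#' @param n list size (default 150).
#' @return Character vector of gene symbols (length <= `n`).
#' @export
selectEnrichmentInput <- function(de, n = 150L) {
  top <- rankTranscripts(de, direction = "increased", k = n,
                         collapse_to_genes = TRUE)
  if (nrow(top) < n) {
    warning("selectEnrichmentInput: only ", nrow(top),
            " increased transcripts available (requested ", n, ")")
  }
  if (any(top$p_fdr >= 0.05)) {
    warning("selectEnrichmentInput: ", sum(top$p_fdr >= 0.05),
            " selected transcript(s) have FDR >= 0.05")
  }
  genes <- top$gene_symbol
  genes[is.na(genes) | genes == ""] <- top$probe_id[is.na(genes) | genes == ""]
  unique(genes)
}

#' Hypergeometric overrepresentation test
#'
#' For each gene set, the one-sided hypergeometric tail probability of
#' observing at least the overlap seen between the query list and the set,
#' drawing `n = |query|` genes from a universe of size `N` containing
#' `K = |set|` set members:
#' \deqn{p = P(X \ge k), \quad X \sim \mathrm{Hypergeom}(N, K, n)}
#' (equivalently the one-sided Fisher exact test of the 2x2 table). Query and
#' sets are intersected with the universe first; empty sets are dropped with
#' a warning. BH adjustment is applied across the sets of the collection and
#' results are sorted by p.
#'
#' @param genes character vector of query gene symbols.
#' @param collection from [readGeneSets()], or a named list of character
#'   vectors.
#' @param universe character vector of background gene symbols; defaults to
#'   the collection's universe.
#' @return A `data.frame`: `set`, `overlap` (k), `set_size` (K),
#'   `query_size` (n), `universe_size` (N), `p`, `p_fdr`,
#'   `overlap_genes` (semicolon-joined).
#' @export
oraTest <- function(genes, collection, universe = NULL) {
  sets <- if (is.list(collection) && !is.null(collection$sets)) collection$sets else collection
  .stopIfNot(is.list(sets) && length(sets) >= 1L && !is.null(names(sets)),
             "oraTest: collection must be a named list of gene sets")
  if (is.null(universe)) universe <- collection$universe
  .stopIfNot(!is.null(universe) && length(universe) >= 1L,
             "oraTest: a gene universe is required")
  universe <- unique(universe)
  query <- unique(intersect(genes, universe))
  .stopIfNot(length(query) >= 1L, "oraTest: empty query after intersection with universe")
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty)) {
    warning("oraTest: dropping ", sum(empty), " empty set(s) after universe intersection")
    sets <- sets[!empty]
  }
  .stopIfNot(length(sets) >= 1L, "oraTest: no non-empty sets")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    K <- length(s)
    ov <- intersect(query, s)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p,
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- benjaminiHochberg(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("set", "overlap", "set_size", "query_size", "universe_size",
          "p", "p_fdr", "overlap_genes")]
}
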