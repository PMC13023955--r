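# Host-miRNA target filtering, hypergeometric gene-set enrichment, and a
# simplified cross-kingdom seed-match scanner against bacterial coding
# sequences. The scanner requires a perfect complement of miRNA seed
# positions 2-8 and deliberately replaces thermodynamic duplex scoring; it
# is labelled "simplified seed match" in all outputs.

#' Expressed miRNA filter
#'
#' Keeps miRNAs whose mean raw count across samples is strictly greater
#' than `min_avg` (a mean of exactly `min_avg` is excluded).
#'
#' @param counts features x samples raw count matrix (miRNA rows).
#' @param min_avg exclusion threshold on the mean (default 5).
#' @return character vector of retained miRNA ids.
#' @export
filter_expressed_mirnas <- function(counts, min_avg = 5) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0) return(character(0))
  keep <- rowMeans(counts) > min_avg
  rownames(counts)[keep]
}

#' Filter target-score rows by context score and percentile
#'
#' Removal follows the strict wording of the conventional rule: a row is
#' removed iff its score is greater than `score_max` or its percentile is
#' less than `pct_min`; boundary rows (score exactly -0.2, percentile
#' exactly 90) are kept. Idempotent.
#'
#' @param rows data.frame with `context_score` and `percentile` columns.
#' @param score_max score threshold (default -0.2).
#' @param pct_min percentile threshold (default 90).
#' @return the retained rows.
#' @export
filter_targets <- function(rows, score_max = -0.2, pct_min = 90) {
  keep <- !(rows$context_score > score_max | rows$percentile < pct_min)
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided upper-tail hypergeometric test per gene set (probability of
#' observing at least the seen overlap between the query and the set,
#' drawing from the universe), BH-corrected across sets.
#'
#' @param query_genes character vector of query gene ids (subset of the
#'   universe).
#' @param gene_sets named list of character vectors (each a subset of the
#'   universe).
#' @param universe character vector of all gene ids.
#' @return data.frame `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `q`.
#' @export
hypergeometric_enrichment <- function(query_genes, gene_sets, universe) {
  query_genes <- unique(query_genes)
  universe <- unique(universe)
  if (!all(query_genes %in% universe)) {
    stop("query genes outside the universe", call. = FALSE)
  }
  N <- length(universe)
  n <- length(query_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- unique(gene_sets[[nm]])
    if (!all(set %in% universe)) {
      stop(sprintf("gene set '%s' outside the universe", nm), call. = FALSE)
    }
    K <- length(set)
    k <- length(intersect(set, query_genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}

#' Simplified cross-kingdom seed-match target scan
#'
#' A hit is any position of a bacterial CDS containing the perfect
#' reverse complement of miRNA seed positions 2-8 (1-based, 5'->3', with
#' T treated as U). This is a declared simplification of thermodynamic
#' hybridization target prediction, sufficient for counting candidate
#' targets per miRNA.
#'
#' @param mirna_sequences named character vector of miRNA sequences
#'   (length >= 8 each).
#' @param bacterial_cds data.frame with `id`, `species`, `category`,
#'   `seq` (as in a `pmi_refs` object).
#' @return data.frame `mirna`, `cds`, `species`, `category`, `n_sites`,
#'   `first_offset`; one row per (miRNA, CDS) pair with at least one site.
#' @export
seed_scan_targets <- function(mirna_sequences, bacterial_cds) {
  if (any(nchar(mirna_sequences) < 8)) {
    stop("all miRNAs must be at least 8 nt", call. = FALSE)
  }
  seed_rc <- rev_comp(toupper(chartr("U", "T", substr(mirna_sequences, 2, 8))))
  rows <- list()
  for (i in seq_along(mirna_sequences)) {
    hits <- .match_scan_cpp(seed_rc[i], bacterial_cds$seq, 0L)
    if (length(hits$ref) == 0) next
    per_cds <- split(hits$start, hits$ref)
    for (r in names(per_cds)) {
      j <- as.integer(r)
      rows[[length(rows) + 1]] <- data.frame(
        mirna = names(mirna_sequences)[i] %||% paste0("mirna", i),
        cds = bacterial_cds$id[j],
        species = bacterial_cds$species[j],
        category = bacterial_cds$category[j],
        n_sites = length(per_cds[[r]]),
        first_offset = min(per_cds[[r]]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(mirna = character(0), cds = character(0),
                      species = character(0), category = character(0),
                      n_sites = integer(0), first_offset = integer(0)))
  }
  do.call(rbind, rows)
}

#' Per-cluster target counts and category proportions
#'
#' @param hits hit table from [seed_scan_targets()].
#' @param mirna_clusters named vector: cluster label per miRNA (every
#'   miRNA in `hits` must be present).
#' @return list with `per_mirna` (targets per miRNA with cluster and a
#'   `top` flag per cluster) and `category_pct` (cluster x category
#'   percentage matrix, rows summing to 100).
#' @export
cluster_target_summary <- function(hits, mirna_clusters) {
  if (!all(hits$mirna %in% names(mirna_clusters))) {
    stop("unclustered miRNA in hit table", call. = FALSE)
  }
  hits$cluster <- mirna_clusters[hits$mirna]
  n_targets <- aggregate(cds ~ mirna + cluster, hits,
                         FUN = function(v) length(unique(v)))
  names(n_targets)[3] <- "n_targets"
  n_targets$top <- FALSE
  for (cl in unique(n_targets$cluster)) {
    i <- which(n_targets$cluster == cl)
    n_targets$top[i[which.max(n_targets$n_targets[i])]] <- TRUE
  }
  tab <- table(hits$cluster, hits$category)
  category_pct <- 100 * prop.table(tab, margin = 1)
  list(per_mirna = n_targets[order(n_targets$cluster,
                                   -n_targets$n_targets), ],
       category_pct = category_pct)
}
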