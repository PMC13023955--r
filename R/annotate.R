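# Hierarchical annotation of collapsed small-RNA reads against a toy
# reference set: ungapped sense-strand matching with one-mismatch tolerance,
# a fixed class priority order, the four-way tsRNA taxonomy, and unique
# rsRNA parent assignment by ascending rRNA length.

CLASS_PRIORITY <- c("rsRNA", "ysRNA", "miRNA", "piRNA", "tsRNA", "snoRNA")

#' Construct mature tRNA sequences from pre-tRNAs
#'
#' Applies the standard maturation rules used when building a mature tRNA
#' reference from genomic tRNA predictions: the annotated intron is spliced
#' out, a `CCA` tail is appended to every 3' end, and histidine tRNAs
#' additionally receive a `G` at the 5' end.
#'
#' @param pre_trnas data.frame with columns `id`, `seq`, `intron_start`,
#'   `intron_end` (1-based inclusive bounds of the intron; `NA` for
#'   intronless tRNAs), `aa` (amino-acid label, e.g. `"His"`), and
#'   optionally `mito` (logical).
#' @return named character vector of mature sequences, in input order.
#' @examples
#' pre <- data.frame(id = "tRNA-His-1", seq = "AAGG", intron_start = NA,
#'                   intron_end = NA, aa = "His")
#' build_mature_trnas(pre)  # "GAAGGCCA"
#' @export
build_mature_trnas <- function(pre_trnas) {
  stopifnot(all(c("id", "seq", "intron_start", "intron_end", "aa") %in%
                  names(pre_trnas)))
  out <- character(nrow(pre_trnas))
  for (i in seq_len(nrow(pre_trnas))) {
    s <- pre_trnas$seq[i]
    a <- pre_trnas$intron_start[i]
    b <- pre_trnas$intron_end[i]
    if (!is.na(a) && !is.na(b)) {
      if (a < 1 || b > nchar(s) || a > b + 1) {
        stop(sprintf("intron interval [%s, %s] out of bounds for %s",
                     a, b, pre_trnas$id[i]), call. = FALSE)
      }
      s <- paste0(substr(s, 1, a - 1), substr(s, b + 1, nchar(s)))
    }
    s <- paste0(s, "CCA")
    if (tolower(pre_trnas$aa[i]) %in% c("his", "histidine")) {
      s <- paste0("G", s)
    }
    out[i] <- s
  }
  names(out) <- pre_trnas$id
  out
}

#' Find all exact / one-mismatch occurrences of a read in references
#'
#' Ungapped sense-strand scan reporting every occurrence with Hamming
#' distance at most `max_mm`. Exact hits sort before one-mismatch hits;
#' within a mismatch level hits are ordered by offset, then reference id.
#'
#' @param query a single read sequence.
#' @param references named character vector of reference sequences.
#' @param max_mm 0 or 1 mismatches tolerated.
#' @return data.frame with columns `parent_id`, `offset` (1-based start),
#'   `mismatches`; zero rows when the read does not occur.
#' @export
match_with_mismatch <- function(query, references, max_mm = 1) {
  stopifnot(is.character(query), length(query) == 1, nchar(query) >= 1,
            length(references) > 0, max_mm %in% c(0, 1))
  if (is.null(names(references))) {
    names(references) <- paste0("ref", seq_along(references))
  }
  hits <- .match_scan_cpp(query, unname(references), as.integer(max_mm))
  df <- data.frame(parent_id = names(references)[hits$ref],
                   offset = hits$start,
                   mismatches = hits$mismatches,
                   stringsAsFactors = FALSE)
  df[order(df$mismatches, df$offset, df$parent_id), , drop = FALSE]
}

#' Categorize a tsRNA by its origin on the parent tRNA
#'
#' A tRNA-derived fragment is labelled by where its alignment sits on the
#' pre- or mature tRNA: `5p` when it starts at the first base of either
#' form, `3p_CCA` when it ends exactly at the mature 3' end (the appended
#' CCA), `3p_pre` when it ends exactly at the pre-tRNA 3' end, otherwise
#' `internal`. When a read qualifies for several categories (e.g. it spans
#' a whole short mature tRNA) precedence is `3p_CCA > 5p > 3p_pre >
#' internal`.
#'
#' @param read read sequence.
#' @param pre_seq pre-tRNA sequence (may be `NA`).
#' @param mature_seq mature tRNA sequence (may be `NA`).
#' @param max_mm mismatch tolerance passed to the matcher.
#' @return one of `"5p"`, `"3p_CCA"`, `"3p_pre"`, `"internal"`.
#' @export
classify_tsrna <- function(read, pre_seq = NA, mature_seq = NA, max_mm = 1) {
  cats <- character(0)
  L <- nchar(read)
  scan_one <- function(seqs, label) {
    h <- .match_scan_cpp(read, seqs, as.integer(max_mm))
    h
  }
  if (!is.na(mature_seq)) {
    h <- .match_scan_cpp(read, mature_seq, as.integer(max_mm))
    for (st in h$start) {
      if (st + L - 1 == nchar(mature_seq)) cats <- c(cats, "3p_CCA")
      if (st == 1) cats <- c(cats, "5p")
    }
  }
  if (!is.na(pre_seq)) {
    h <- .match_scan_cpp(read, pre_seq, as.integer(max_mm))
    for (st in h$start) {
      if (st == 1) cats <- c(cats, "5p")
      if (st + L - 1 == nchar(pre_seq)) cats <- c(cats, "3p_pre")
    }
  }
  if (length(cats) == 0) {
    if ((is.na(mature_seq) || nrow_hits(read, mature_seq, max_mm) == 0) &&
        (is.na(pre_seq) || nrow_hits(read, pre_seq, max_mm) == 0)) {
      stop("read has no hit on the supplied tRNA sequences", call. = FALSE)
    }
    return("internal")
  }
  for (lev in c("3p_CCA", "5p", "3p_pre")) {
    if (lev %in% cats) return(lev)
  }
  "internal"
}

nrow_hits <- function(read, seq, max_mm) {
  length(.match_scan_cpp(read, seq, as.integer(max_mm))$start)
}

#' Unique rsRNA parent by ascending rRNA length
#'
#' When a read matches several rRNAs the parent is the shortest one, so
#' each rRNA-derived fragment is annotated once (a fragment assigned to a
#' short rRNA is not re-aligned to longer rRNAs that contain the same
#' region). Uniqueness follows from the pairwise-distinct rRNA lengths.
#'
#' @param hit_parents character vector of rRNA ids the read hits.
#' @param rrnas named character vector of all rRNA sequences.
#' @return the chosen parent id.
#' @export
assign_rsrna_parent <- function(hit_parents, rrnas) {
  stopifnot(length(hit_parents) >= 1, all(hit_parents %in% names(rrnas)))
  lens <- nchar(rrnas[hit_parents])
  hit_parents[which.min(lens)]
}

#' Annotate a collapsed small-RNA library
#'
#' Each read (15-45 nt; reads outside the window are dropped and counted)
#' is tested against the reference classes in the fixed priority order
#' rRNA, YRNA, miRNA, piRNA, tRNA (pre and mature), snoRNA; the first class
#' with an exact or one-mismatch hit wins. Reads that hit no class but do
#' match the host genome are `other_ncRNA`; reads matching neither are
#' `unmapped` (exogenous candidates). tsRNAs are sub-categorized by origin
#' (`5p`, `3p_CCA`, `3p_pre`, `internal`) and split into `tsRNA` /
#' `mt-tsRNA` by the mitochondrial flag of the parent tRNA; rsRNA parents
#' are assigned by ascending rRNA length. Ties within a class are broken by
#' fewest mismatches, then smallest offset, then lexicographic parent id.
#'
#' @param lib a library as produced by [generate_srna_libraries()] or
#'   [read_library_tsv()]: list with `reads` (data.frame `sequence`,
#'   `count`).
#' @param refs a reference set from [generate_toy_references()].
#' @param max_mm mismatch tolerance (0 or 1).
#' @return data.frame with one row per retained read: `sequence`, `count`,
#'   `class`, `parent_id`, `tsrna_category`, `mismatches`; the number of
#'   reads dropped for length is in `attr(, "n_length_dropped")`.
#' @export
annotate_library <- function(lib, refs, max_mm = 1) {
  reads <- lib$reads
  stopifnot(is.data.frame(reads), all(c("sequence", "count") %in% names(reads)))
  len <- nchar(reads$sequence)
  keep <- len >= 15 & len <= 45
  n_dropped <- sum(reads$count[!keep])
  reads <- reads[keep, , drop = FALSE]

  mature <- refs$mature_trnas
  pre <- setNames(refs$pre_trnas$seq, refs$pre_trnas$id)
  mito <- setNames(refs$pre_trnas$mito %||% rep(FALSE, nrow(refs$pre_trnas)),
                   refs$pre_trnas$id)
  class_refs <- list(
    rsRNA = refs$rrnas,
    ysRNA = refs$yrnas,
    miRNA = refs$mirnas,
    piRNA = refs$pirnas,
    tsRNA = c(pre, setNames(mature, paste0(names(mature), "::mature"))),
    snoRNA = refs$snornas
  )

  n <- nrow(reads)
  cls <- character(n); parent <- character(n)
  cat_ts <- rep("n/a", n); mm_used <- integer(n)

  for (i in seq_len(n)) {
    q <- reads$sequence[i]
    assigned <- FALSE
    for (cl in CLASS_PRIORITY) {
      hits <- match_with_mismatch(q, class_refs[[cl]], max_mm)
      if (nrow(hits) == 0) next
      assigned <- TRUE
      if (cl == "rsRNA") {
        par <- assign_rsrna_parent(unique(hits$parent_id), refs$rrnas)
        mmv <- min(hits$mismatches[hits$parent_id == par])
      } else if (cl == "tsRNA") {
        base <- sub("::mature$", "", hits$parent_id)
        ord <- order(hits$mismatches, hits$offset, base)
        par <- base[ord[1]]
        mmv <- hits$mismatches[ord[1]]
        cat_ts[i] <- classify_tsrna(
          q,
          pre_seq = if (par %in% names(pre)) pre[[par]] else NA,
          mature_seq = if (par %in% names(mature)) mature[[par]] else NA,
          max_mm = max_mm)
        if (isTRUE(mito[[par]])) cl <- "mt-tsRNA"
      } else {
        par <- hits$parent_id[1]
        mmv <- hits$mismatches[1]
      }
      cls[i] <- cl; parent[i] <- par; mm_used[i] <- mmv
      break
    }
    if (!assigned) {
      if (.match_any_cpp(q, unname(refs$host_genome), as.integer(max_mm))) {
        cls[i] <- "other_ncRNA"; parent[i] <- "host_genome"; mm_used[i] <- 0L
      } else {
        cls[i] <- "unmapped"; parent[i] <- NA_character_; mm_used[i] <- 0L
      }
    }
  }
  out <- data.frame(sequence = reads$sequence, count = reads$count,
                    class = cls, parent_id = parent,
                    tsrna_category = cat_ts, mismatches = mm_used,
                    stringsAsFactors = FALSE)
  attr(out, "n_length_dropped") <- n_dropped
  attr(out, "sample_id") <- lib$sample_id %||% NA_character_
  out
}

#' Build raw and RPM count matrices from per-library annotations
#'
#' @param annotations named list of annotation data.frames (one per sample,
#'   as from [annotate_library()]).
#' @param by `"parent"` (default) to count per parent feature or `"class"`.
#' @return list with `counts` (features x samples integer matrix), `rpm`,
#'   and `feature_class` (class label per feature). RPM normalizes by the
#'   per-sample total over mapped features, so mapped columns sum to 1e6;
#'   `unmapped` reads are excluded from the denominator.
#' @export
build_count_matrix <- function(annotations, by = c("parent", "class")) {
  by <- match.arg(by)
  key <- function(a) {
    if (by == "parent") {
      ifelse(a$class %in% c("tsRNA", "mt-tsRNA"),
             paste0(a$parent_id, ":", a$tsrna_category),
             ifelse(is.na(a$parent_id), "unmapped", a$parent_id))
    } else {
      a$class
    }
  }
  tabs <- lapply(annotations, function(a) {
    tapply(a$count, list(feat = key(a), class = a$class), sum)
  })
  feats <- sort(unique(unlist(lapply(annotations, function(a) key(a)))))
  samples <- names(annotations) %||% paste0("S", seq_along(annotations))
  counts <- matrix(0L, length(feats), length(samples),
                   dimnames = list(feats, samples))
  feature_class <- setNames(rep(NA_character_, length(feats)), feats)
  for (j in seq_along(annotations)) {
    a <- annotations[[j]]
    k <- key(a)
    agg <- tapply(a$count, k, sum)
    counts[names(agg), j] <- as.integer(agg)
    feature_class[k] <- a$class
  }
  mapped <- feature_class != "unmapped"
  rpm <- compute_rpm(counts, mapped = mapped)
  list(counts = counts, rpm = rpm, feature_class = feature_class)
}

#' Reads-per-million normalization over mapped features
#'
#' @param counts features x samples non-negative count matrix.
#' @param mapped logical vector marking features that count towards the
#'   per-sample mapped total (default: all).
#' @return matrix of the same shape; mapped features in each column sum to
#'   1e6.
#' @export
compute_rpm <- function(counts, mapped = rep(TRUE, nrow(counts))) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  tot <- colSums(counts[mapped, , drop = FALSE])
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0] %||% which(tot == 0)
    stop(sprintf("sample(s) with zero mapped reads: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sweep(counts, 2, tot, function(x, t) x * 1e6 / t)
}

#' Count-weighted fraction of reads matching a genome
#'
#' @param lib a collapsed-read library (list with `reads`).
#' @param genome_sequences character vector of genome sequences.
#' @param max_mm mismatch tolerance.
#' @return fraction in `[0, 1]`.
#' @export
genome_match_rate <- function(lib, genome_sequences, max_mm = 1) {
  reads <- lib$reads
  if (is.null(reads) || nrow(reads) == 0) stop("empty library", call. = FALSE)
  hit <- .match_any_cpp(reads$sequence, unname(genome_sequences),
                        as.integer(max_mm))
  sum(reads$count[hit]) / sum(reads$count)
}

#' Count-weighted read length histogram (15-45 nt)
#'
#' @param lib a collapsed-read library.
#' @param annotation optional annotation data.frame used with
#'   `class_filter`.
#' @param class_filter optional character vector of classes to include.
#' @return named integer vector over lengths 15..45 summing to the total
#'   count of included reads.
#' @export
length_distribution <- function(lib, annotation = NULL, class_filter = NULL) {
  reads <- lib$reads
  if (!is.null(class_filter)) {
    stopifnot(!is.null(annotation))
    keep <- annotation$class %in% class_filter
    reads <- merge(reads, annotation[keep, c("sequence", "class")],
                   by = "sequence")
  }
  h <- setNames(integer(31), 15:45)
  if (nrow(reads) > 0) {
    len <- nchar(reads$sequence)
    ok <- len >= 15 & len <= 45
    agg <- tapply(reads$count[ok], len[ok], sum)
    h[names(agg)] <- as.integer(agg)
  }
  h
}
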