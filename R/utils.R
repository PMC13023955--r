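# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible stage seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own seed
#' deterministically from one global integer seed and a stage label, so a
#' single value reproduces a full run while stages stay decoupled (adding a
#' stage never shifts another stage's stream). The label is hashed by a
#' simple polynomial byte hash modulo `2^31 - 1`.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647  # 2^31 - 1 (prime)
  h <- as.double(seed %% m)
  for (b in utf8ToInt(stage)) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stop_if_not_number <- function(x, what, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 what, format(lo), format(hi)), call. = FALSE)
  }
  invisible(x)
}

assert_alphabet <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T} (first offender: %s)",
                 what, seqs[which(bad)[1]]), call. = FALSE)
  }
  invisible(seqs)
}

# Consistent numeric formatting so repeated runs produce byte-identical
# artifacts regardless of options(digits).
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

# Write a data.frame as TSV with `#`-prefixed metadata header lines.
write_table_meta <- function(df, path, meta = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (m in names(meta)) {
    writeLines(sprintf("# %s: %s", m, meta[[m]]), con, sep = "\n")
  }
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- fmt_num(df[[j]])
  writeLines(paste(colnames(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out) > 0) {
    lines <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

read_table_meta <- function(path, sep = "\t") {
  read.delim(path, sep = sep, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

rev_comp <- function(seqs) {
  chartr("ACGT", "TGCA", vapply(strsplit(seqs, ""), function(s) {
    paste(rev(s), collapse = "")
  }, character(1)))
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
}

# all k-mers of a set of sequences (as a character vector, possibly huge --
# used only on toy-scale references)
kmer_set <- function(seqs, k) {
  out <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  unique(out)
}
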