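# Independent brute-force oracles used to cross-check the compiled matcher
# and the annotator. Implemented in plain vectorized R (integer window
# matrices), deliberately sharing no code with the package's C++ scanner.

# all 0/1-mismatch occurrences of q in one reference string
oracle_scan_one <- function(q, ref, max_mm) {
  L <- nchar(q)
  n <- nchar(ref)
  if (n < L) return(data.frame(offset = integer(0), mismatches = integer(0)))
  qi <- utf8ToInt(q)
  ri <- utf8ToInt(ref)
  nw <- n - L + 1
  W <- matrix(ri[outer(0:(L - 1), seq_len(nw), "+")], nrow = L)
  mm <- colSums(W != qi)
  hit <- which(mm <= max_mm)
  data.frame(offset = hit, mismatches = as.integer(mm[hit]))
}

oracle_scan <- function(q, refs, max_mm) {
  rows <- lapply(seq_along(refs), function(i) {
    h <- oracle_scan_one(q, refs[[i]], max_mm)
    if (nrow(h) == 0) return(NULL)
    data.frame(parent_id = names(refs)[i], offset = h$offset,
               mismatches = h$mismatches, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(parent_id = character(0), offset = integer(0),
                      mismatches = integer(0)))
  }
  out[order(out$mismatches, out$offset, out$parent_id), , drop = FALSE]
}

# Full independent annotator: enumerates every (class, parent) hit and
# applies the documented priority and tie-break rules.
oracle_annotate <- function(lib, refs, max_mm = 1) {
  pre <- setNames(refs$pre_trnas$seq, refs$pre_trnas$id)
  mature <- refs$mature_trnas
  mito <- setNames(refs$pre_trnas$mito, refs$pre_trnas$id)
  class_refs <- list(
    rsRNA = refs$rrnas, ysRNA = refs$yrnas, miRNA = refs$mirnas,
    piRNA = refs$pirnas,
    tsRNA = c(pre, setNames(mature, paste0(names(mature), "::mature"))),
    snoRNA = refs$snornas)
  reads <- lib$reads[nchar(lib$reads$sequence) >= 15 &
                       nchar(lib$reads$sequence) <= 45, , drop = FALSE]
  out <- lapply(seq_len(nrow(reads)), function(i) {
    q <- reads$sequence[i]
    for (cl in c("rsRNA", "ysRNA", "miRNA", "piRNA", "tsRNA", "snoRNA")) {
      hits <- oracle_scan(q, class_refs[[cl]], max_mm)
      if (nrow(hits) == 0) next
      if (cl == "rsRNA") {
        lens <- nchar(refs$rrnas[unique(hits$parent_id)])
        par <- unique(hits$parent_id)[which.min(lens)]
      } else if (cl == "tsRNA") {
        base <- sub("::mature$", "", hits$parent_id)
        ord <- order(hits$mismatches, hits$offset, base)
        par <- base[ord[1]]
        cl <- if (isTRUE(mito[[par]])) "mt-tsRNA" else "tsRNA"
      } else {
        par <- hits$parent_id[1]
      }
      cat_ts <- "n/a"
      if (cl %in% c("tsRNA", "mt-tsRNA")) {
        cats <- character(0)
        L <- nchar(q)
        if (par %in% names(mature)) {
          h <- oracle_scan_one(q, mature[[par]], max_mm)
          for (st in h$offset) {
            if (st + L - 1 == nchar(mature[[par]])) cats <- c(cats, "3p_CCA")
            if (st == 1) cats <- c(cats, "5p")
          }
        }
        if (par %in% names(pre)) {
          h <- oracle_scan_one(q, pre[[par]], max_mm)
          for (st in h$offset) {
            if (st == 1) cats <- c(cats, "5p")
            if (st + L - 1 == nchar(pre[[par]])) cats <- c(cats, "3p_pre")
          }
        }
        cat_ts <- "internal"
        for (lev in c("3p_CCA", "5p", "3p_pre")) {
          if (lev %in% cats) { cat_ts <- lev; break }
        }
      }
      return(data.frame(sequence = q, class = cl, parent_id = par,
                        tsrna_category = cat_ts, stringsAsFactors = FALSE))
    }
    host <- oracle_scan(q, refs$host_genome, max_mm)
    if (nrow(host) > 0) {
      data.frame(sequence = q, class = "other_ncRNA",
                 parent_id = "host_genome", tsrna_category = "n/a",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sequence = q, class = "unmapped", parent_id = NA_character_,
                 tsrna_category = "n/a", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

# step-up BH by its textbook definition: q_(i) = min_{j >= i} p_(j) * n / j
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    j <- i:n
    q_sorted[i] <- min(pmin(p[o][j] * n / j, 1))
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# hypergeometric upper tail by explicit pmf summation
oracle_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# exact Shapley by permutation enumeration (p <= 5)
oracle_shapley_perm <- function(predict_fun, x, background) {
  p <- length(x)
  perms <- permute_all(seq_len(p))
  phi <- numeric(p)
  v <- function(S) {
    blk <- background
    for (j in S) blk[, j] <- x[j]
    mean(predict_fun(blk))
  }
  for (pi in seq_len(nrow(perms))) {
    prev <- integer(0)
    for (j in perms[pi, ]) {
      phi[j] <- phi[j] + (v(c(prev, j)) - v(prev))
      prev <- c(prev, j)
    }
  }
  phi / nrow(perms)
}

permute_all <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- permute_all(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}
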