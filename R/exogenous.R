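# Exogenous (host-unmapped) small-RNA analysis: extraction, abundance
# filtering, a simplified negative-binomial Wald test with median-of-ratios
# size factors, exact-match taxonomy, and species composition /
# genome-match trajectories.

#' Extract host-unmapped fragments across libraries
#'
#' Fragments with no exact or one-mismatch hit anywhere in the host genome
#' are tabulated across samples (candidate microbial reads).
#'
#' @param libs list of collapsed-read libraries.
#' @param host_genome character vector of host genome sequences.
#' @param max_mm mismatch tolerance for the host scan.
#' @return data.frame: `fragment`, one count column per sample, `total`.
#' @export
extract_unmapped <- function(libs, host_genome, max_mm = 1) {
  seqs <- sort(unique(unlist(lapply(libs, function(l) l$reads$sequence))))
  if (length(seqs) == 0) {
    return(data.frame(fragment = character(0), total = numeric(0)))
  }
  hit <- .match_any_cpp(seqs, unname(host_genome), as.integer(max_mm))
  exo <- seqs[!hit]
  samples0 <- vapply(libs, function(l) l$sample_id %||% "S", character(1))
  if (length(exo) == 0) {
    out <- data.frame(fragment = character(0), stringsAsFactors = FALSE)
    for (s in samples0) out[[s]] <- numeric(0)
    out$total <- numeric(0)
    return(out)
  }
  samples <- vapply(libs, function(l) l$sample_id %||% "S", character(1))
  counts <- sapply(libs, function(l) {
    v <- l$reads$count[match(exo, l$reads$sequence)]
    ifelse(is.na(v), 0, v)
  })
  counts <- matrix(counts, nrow = length(exo),
                   dimnames = list(NULL, samples))
  out <- data.frame(fragment = exo, counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$total <- rowSums(counts)
  out[order(-out$total, out$fragment), , drop = FALSE]
}

#' Exclude low-abundance fragments
#'
#' Strict rule: rows with `total < min_total` are removed (a total of
#' exactly `min_total` is retained).
#'
#' @param table fragment table with a `total` column.
#' @param min_total threshold (default 1000).
#' @return the filtered table; removed rows in `attr(, "removed")`.
#' @export
filter_low_abundance <- function(table, min_total = 1000) {
  keep <- table$total >= min_total
  out <- table[keep, , drop = FALSE]
  attr(out, "removed") <- table[!keep, , drop = FALSE]
  out
}

#' Median-of-ratios size factors
#'
#' For every sample, the median over all-nonzero fragments of the ratio
#' of its count to the fragment's geometric mean, rescaled so the size
#' factors have geometric mean one.
#'
#' @param counts fragments x samples count matrix.
#' @return numeric vector of size factors (one per sample, all > 0).
#' @export
size_factors_median_ratio <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no fragment with nonzero counts in all samples",
                      call. = FALSE)
  lg <- log(counts[pos, , drop = FALSE])
  gm <- rowMeans(lg)
  s <- exp(apply(lg - gm, 2, median))
  s <- s / exp(mean(log(s)))
  s
}

#' Negative-binomial Wald test for two-group differential abundance
#'
#' A simplified count-based differential test: counts are normalized with
#' median-of-ratios size factors; a per-fragment dispersion is estimated
#' by the method of moments from the pooled within-group variance of the
#' normalized counts; group means give the log2 fold change; the Wald
#' statistic uses the delta-method standard error from the per-group NB
#' variance `mu_g + alpha*mu_g^2`, referred to a t distribution with
#' `n1 + n2 - 2` degrees of freedom as a small-sample correction (a
#' normal reference is visibly anti-conservative at n = 5 per group);
#' BH correction is applied across fragments. The significance flag
#' requires fold change > 2 (either direction) and q < 0.01. No
#' dispersion or fold-change shrinkage is applied. In the variance the
#' raw moment estimate is used even when it is sub-Poisson (negative),
#' with a positivity floor on the total variance -- flooring the
#' dispersion itself at the Poisson bound breaks finite-sample
#' calibration; the reported `dispersion` column is floored at 1e-8.
#' Groups with all-zero counts for a fragment are handled by flooring
#' the group mean at `mu_floor` normalized counts rather than erroring.
#'
#' @param counts fragments x samples matrix (rownames = fragment ids).
#' @param groups factor/character of length `ncol(counts)` with exactly
#'   two levels; the fold change is level 2 vs level 1.
#' @param fc_threshold,q_threshold significance thresholds.
#' @param mu_floor pseudo-mean floor for all-zero groups.
#' @return data.frame `fragment`, `log2fc`, `mean_a`, `mean_b`,
#'   `dispersion`, `p`, `q`, `significant`; size factors in
#'   `attr(, "size_factors")`.
#' @export
nb_wald_test <- function(counts, groups, fc_threshold = 2,
                         q_threshold = 0.01, mu_floor = 0.5) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(groups) < 2)) stop("need >= 2 samples per group",
                                   call. = FALSE)
  s <- size_factors_median_ratio(counts)
  norm <- sweep(counts, 2, s, "/")
  ia <- groups == levels(groups)[1]
  ib <- !ia
  na <- sum(ia); nb <- sum(ib)
  mu_a <- rowMeans(norm[, ia, drop = FALSE])
  mu_b <- rowMeans(norm[, ib, drop = FALSE])
  # moment dispersion from pooled within-group variance of normalized
  # counts: Var = mu + alpha mu^2
  va <- apply(norm[, ia, drop = FALSE], 1, var)
  vb <- apply(norm[, ib, drop = FALSE], 1, var)
  vpool <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  mu_pool <- (mu_a + mu_b) / 2
  alpha_raw <- (vpool - mu_pool) / mu_pool^2
  alpha_raw[!is.finite(alpha_raw)] <- 0
  alpha <- pmax(alpha_raw, 1e-8)
  fa <- pmax(mu_a, mu_floor)
  fb <- pmax(mu_b, mu_floor)
  log2fc <- log2(fb / fa)
  # delta-method variance of the log2 group mean under NB sampling; the
  # raw (possibly sub-Poisson) moment dispersion keeps the statistic
  # calibrated, with a positivity floor on the total variance
  var_a <- pmax(fa + alpha_raw * fa^2, 1e-8) / na
  var_b <- pmax(fb + alpha_raw * fb^2, 1e-8) / nb
  se <- sqrt(var_a / fa^2 + var_b / fb^2) / log(2)
  z <- ifelse(se == 0 & log2fc == 0, 0, log2fc / se)
  p <- 2 * pt(-abs(z), df = na + nb - 2)
  p[log2fc == 0] <- 1
  q <- bh_adjust(p)
  data.frame(
    fragment = rownames(counts) %||% seq_len(nrow(counts)),
    log2fc = log2fc, mean_a = mu_a, mean_b = mu_b, dispersion = alpha,
    p = p, q = q,
    significant = abs(log2fc) > log2(fc_threshold) & q < q_threshold,
    stringsAsFactors = FALSE) -> out
  attr(out, "size_factors") <- s
  rownames(out) <- NULL
  out
}

#' Assign bacterial taxonomy by exact full-length matching
#'
#' A fragment is labelled with the species whose genome contains it
#' verbatim (sense strand). Fragments found in several species are
#' `ambiguous`; fragments found in none are `unassigned`. On toy
#' references this exact rule is strictly stronger than coverage/identity
#' alignment filters.
#'
#' @param fragments character vector of fragment sequences.
#' @param bacterial_genomes named character vector (names = species).
#' @return data.frame `fragment`, `species`.
#' @export
assign_taxonomy <- function(fragments, bacterial_genomes) {
  sp <- names(bacterial_genomes)
  hits <- sapply(sp, function(s) {
    .match_any_cpp(fragments, unname(bacterial_genomes[s]), 0L)
  })
  hits <- matrix(hits, nrow = length(fragments), dimnames = list(NULL, sp))
  n_hit <- rowSums(hits)
  species <- rep("unassigned", length(fragments))
  one <- n_hit == 1
  species[one] <- sp[apply(hits[one, , drop = FALSE], 1, which.max)]
  species[n_hit > 1] <- "ambiguous"
  data.frame(fragment = fragments, species = species,
             stringsAsFactors = FALSE)
}

#' Species composition of assigned fragments
#'
#' Read-count-weighted percentages over species-assigned fragments
#' (`ambiguous` / `unassigned` mass reported separately); a
#' fragment-weighted column is included since per-fragment and per-read
#' summaries can differ.
#'
#' @param table fragment table with `total` counts.
#' @param taxonomy result of [assign_taxonomy()] for the same fragments.
#' @return data.frame `species`, `percent` (read-weighted),
#'   `percent_fragments`, `n_fragments`; unassigned/ambiguous shares in
#'   attributes.
#' @export
species_composition <- function(table, taxonomy) {
  m <- merge(table[, c("fragment", "total")], taxonomy, by = "fragment")
  assigned <- !(m$species %in% c("ambiguous", "unassigned"))
  if (!any(assigned)) stop("no fragment could be assigned", call. = FALSE)
  a <- m[assigned, ]
  reads <- tapply(a$total, a$species, sum)
  frags <- table(a$species)
  out <- data.frame(
    species = names(reads),
    percent = 100 * as.numeric(reads) / sum(reads),
    percent_fragments = 100 * as.numeric(frags[names(reads)]) / sum(frags),
    n_fragments = as.integer(frags[names(reads)]),
    stringsAsFactors = FALSE)
  out <- out[order(-out$percent), ]
  rownames(out) <- NULL
  attr(out, "unassigned_reads") <- sum(m$total[m$species == "unassigned"])
  attr(out, "ambiguous_reads") <- sum(m$total[m$species == "ambiguous"])
  out
}

#' Genome match-rate trajectory for one species
#'
#' Count-weighted fraction of each library matching the species genome
#' (exact or one mismatch), aggregated per time point as mean and sd.
#'
#' @param libs list of libraries with `timepoint` metadata.
#' @param species_genome genome sequence(s) of the species.
#' @return data.frame `timepoint`, `mean_rate`, `sd_rate`, `n`.
#' @export
species_match_trajectory <- function(libs, species_genome) {
  rates <- vapply(libs, function(l) {
    genome_match_rate(l, species_genome)
  }, numeric(1))
  tps <- vapply(libs, function(l) as.numeric(l$timepoint), numeric(1))
  if (any(is.na(tps))) stop("libraries lack time point metadata",
                            call. = FALSE)
  agg <- split(rates, tps)
  data.frame(
    timepoint = as.numeric(names(agg)),
    mean_rate = vapply(agg, mean, numeric(1)),
    sd_rate = vapply(agg, sd, numeric(1)),
    n = lengths(agg), row.names = NULL)
}
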