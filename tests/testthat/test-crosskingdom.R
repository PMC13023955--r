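# Target filtering boundaries, hypergeometric enrichment and the seed-match
# scanner.

test_that("expressed-miRNA filter excludes a mean of exactly five", {
  counts <- rbind(m1 = rep(5, 4), m2 = c(5, 5, 5, 6), m3 = rep(0, 4))
  keep <- filter_expressed_mirnas(counts)
  expect_equal(keep, "m2")
  expect_equal(filter_expressed_mirnas(counts[0, , drop = FALSE]),
               character(0))
})

test_that("target filtering keeps boundary rows and is idempotent", {
  rows <- data.frame(
    mirna = "m", gene = c("g1", "g2", "g3", "g4"),
    context_score = c(-0.35, -0.10, -0.35, -0.2),
    percentile = c(95, 95, 80, 90))
  out <- filter_targets(rows)
  expect_setequal(out$gene, c("g1", "g4"))  # boundary (-0.2, 90) kept
  expect_equal(filter_targets(out), out)
  expect_equal(nrow(filter_targets(rows[0, ])), 0)
})

test_that("hypergeometric enrichment equals brute-force tail sums", {
  universe <- paste0("g", 1:10)
  sets <- list(hit = paste0("g", 1:5))
  res <- hypergeometric_enrichment(paste0("g", 1:5), sets, universe)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)

  # k = 0 with small overlap expectation: upper tail includes >= 0 => p = 1
  res0 <- hypergeometric_enrichment("g10", list(s = paste0("g", 1:2)),
                                    universe)
  expect_equal(res0$p, 1)

  set.seed(9)
  for (i in 1:40) {
    N <- sample(8:30, 1)
    uni <- paste0("u", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    set <- sample(uni, K)
    query <- sample(uni, N)[seq_len(n)]
    res <- hypergeometric_enrichment(query, list(s = set), uni)
    k <- length(intersect(query, set))
    expect_equal(res$p, oracle_hyper_tail(k, K, N, n), tolerance = 1e-12)
  }
  expect_error(hypergeometric_enrichment("zzz", list(s = "g1"), universe),
               "universe")
})

test_that("seed scan finds the reverse complement of positions 2-8", {
  mir <- c(m1 = "UGAGGUAGUAGGUUGUAUAGUU")  # U alphabet accepted
  seed7 <- substr(chartr("U", "T", mir), 2, 8)         # GAGGTAG
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seed7), "")[[1]]),
              collapse = "")
  cds <- data.frame(id = c("c1", "c2"), species = "s", category = "other",
                    seq = c(paste0("AAAA", rc, "GGGG"),
                            strrep("AT", 20)),
                    stringsAsFactors = FALSE)
  hits <- seed_scan_targets(mir, cds)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$cds, "c1")
  expect_equal(hits$first_offset, 5)
  expect_equal(hits$n_sites, 1)
  expect_error(seed_scan_targets(c(short = "ACGT"), cds), "8 nt")
})

test_that("a CDS equal to the full reverse complement is always hit", {
  mir <- c(m1 = "ACGGUUACGGAUCCGAUAGG")
  mir_dna <- chartr("U", "T", mir)
  rc_full <- paste(rev(strsplit(chartr("ACGT", "TGCA", mir_dna), "")[[1]]),
                   collapse = "")
  cds <- data.frame(id = "c", species = "s", category = "other",
                    seq = rc_full, stringsAsFactors = FALSE)
  expect_gte(seed_scan_targets(mir, cds)$n_sites, 1)
})

test_that("seed scan hit counts equal an exhaustive R-side 7-mer scan", {
  set.seed(12)
  refs <- fixture_refs()
  cds <- refs$bacterial_cds
  mirs <- refs$mirnas[1:8]
  hits <- seed_scan_targets(mirs, cds)
  for (i in seq_along(mirs)) {
    seed7 <- substr(mirs[i], 2, 8)
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seed7), "")[[1]]),
                collapse = "")
    for (j in seq_len(nrow(cds))) {
      n_want <- length(gregexpr(rc, cds$seq[j], fixed = TRUE)[[1]])
      if (gregexpr(rc, cds$seq[j], fixed = TRUE)[[1]][1] == -1) n_want <- 0
      got <- hits$n_sites[hits$mirna == names(mirs)[i] &
                            hits$cds == cds$id[j]]
      expect_equal(if (length(got)) got else 0, n_want)
    }
  }
})

test_that("no cross-boundary hits arise from CDS concatenation", {
  mir <- c(m1 = "AACCGGTTAACCGGTTAACC")
  seed_rc <- {
    s7 <- substr(mir, 2, 8)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s7), "")[[1]]), collapse = "")
  }
  left <- substr(seed_rc, 1, 3)
  right <- substr(seed_rc, 4, 7)
  cds <- data.frame(id = c("a", "b"), species = "s", category = "other",
                    seq = c(paste0(strrep("G", 12), left),
                            paste0(right, strrep("C", 12))),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(seed_scan_targets(mir, cds)), 0)
})

test_that("cluster summary counts targets and normalizes category shares", {
  hits <- data.frame(
    mirna = c("m1", "m1", "m2", "m3"),
    cds = c("c1", "c2", "c1", "c3"),
    species = "s",
    category = c("metabolic enzyme", "virulence factor",
                 "metabolic enzyme", "other"),
    n_sites = c(1, 2, 1, 1), first_offset = 1)
  clusters <- c(m1 = "cluster1", m2 = "cluster1", m3 = "cluster2")
  out <- cluster_target_summary(hits, clusters)
  expect_equal(sum(out$per_mirna$top[out$per_mirna$cluster == "cluster1"]), 1)
  expect_equal(out$per_mirna$n_targets[out$per_mirna$mirna == "m1"], 2)
  expect_equal(unname(rowSums(out$category_pct)), rep(100, 2))
  # single-category cluster is 100% that category
  expect_equal(unname(out$category_pct["cluster2", "other"]), 100)
  expect_error(cluster_target_summary(hits, clusters[1:2]), "unclustered")
})
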