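# Reference construction rules, tsRNA taxonomy, rsRNA assignment, class
# priority and count-matrix normalization.

test_that("mature tRNA construction applies splice, CCA and His-G rules", {
  pre <- data.frame(
    id = c("t1", "tHis", "t3"),
    seq = c("AAGGTT", "AAGG", "AAGGTT"),
    intron_start = c(3L, NA, 1L),
    intron_end = c(4L, NA, 6L),
    aa = c("Gly", "His", "Gly"),
    stringsAsFactors = FALSE)
  m <- build_mature_trnas(pre)
  expect_equal(unname(m["t1"]), "AATTCCA")
  expect_equal(unname(m["tHis"]), "GAAGGCCA")
  expect_equal(unname(m["t3"]), "CCA")  # whole-sequence intron

  bad <- pre[1, ]; bad$intron_end <- 10L
  expect_error(build_mature_trnas(bad), "out of bounds")
})

test_that("tsRNA categories follow the positional definitions and precedence", {
  mature <- "GGGAAACCCTTTCCA"
  expect_equal(classify_tsrna("GGGAAACC", mature_seq = mature), "5p")
  expect_equal(classify_tsrna("TTTCCA", mature_seq = mature), "3p_CCA")
  expect_equal(classify_tsrna("AAACCCT", mature_seq = mature), "internal")
  # read spanning the whole mature tRNA: 3p_CCA precedence over 5p
  expect_equal(classify_tsrna(mature, mature_seq = mature), "3p_CCA")
  pre <- "GGGAAACCCTTTGGA"
  expect_equal(classify_tsrna("TTTGGA", pre_seq = pre), "3p_pre")
  expect_error(classify_tsrna("CCCCCCCC", mature_seq = mature), "no hit")
})

test_that("rsRNA parent is the shortest matching rRNA", {
  rrnas <- c("rRNA-5.8S" = paste(rep("A", 150), collapse = ""),
             "rRNA-45S" = paste(rep("A", 1200), collapse = ""))
  expect_equal(assign_rsrna_parent(c("rRNA-45S", "rRNA-5.8S"), rrnas),
               "rRNA-5.8S")
  expect_equal(assign_rsrna_parent("rRNA-45S", rrnas), "rRNA-45S")
  # random multi-hit cases equal the min-by-length rule
  set.seed(1)
  lens <- sample(100:2000, 10)
  rr <- setNames(vapply(lens, function(L) paste(rep("C", L), collapse = ""),
                        character(1)), paste0("r", 1:10))
  for (i in 1:20) {
    hits <- sample(names(rr), sample(2:6, 1))
    expect_equal(assign_rsrna_parent(hits, rr),
                 hits[which.min(nchar(rr[hits]))])
  }
})

test_that("class priority, host fallback and length window behave as specified", {
  refs <- fixture_refs()
  # read present in both a miRNA and a piRNA reference: miRNA wins
  mir <- refs$mirnas[[1]]
  refs2 <- refs
  refs2$pirnas <- c(refs$pirnas,
                    planted = paste0("AA", mir, "GG"))
  lib <- list(sample_id = "t", reads = data.frame(
    sequence = mir, count = 3L, stringsAsFactors = FALSE))
  ann <- annotate_library(lib, refs2)
  expect_equal(ann$class, "miRNA")

  # bacterial-only read is unmapped
  bac <- substr(refs$bacterial_genomes[[1]], 100, 124)
  lib2 <- list(sample_id = "t", reads = data.frame(
    sequence = bac, count = 1L, stringsAsFactors = FALSE))
  expect_equal(annotate_library(lib2, refs)$class, "unmapped")

  # reads outside 15-45 nt are dropped and counted
  lib3 <- list(sample_id = "t", reads = data.frame(
    sequence = c("ACGTACGTACGT", mir), count = c(5L, 1L),
    stringsAsFactors = FALSE))
  ann3 <- annotate_library(lib3, refs)
  expect_equal(nrow(ann3), 1)
  expect_equal(attr(ann3, "n_length_dropped"), 5)
})

test_that("annotation is invariant to read order", {
  refs <- fixture_refs()
  lib <- fixture_libs()[[1]]
  lib_small <- list(sample_id = "s",
                    reads = head(lib$reads[order(lib$reads$sequence), ], 80))
  rev_lib <- list(sample_id = "s",
                  reads = lib_small$reads[rev(seq_len(80)), ])
  a1 <- annotate_library(lib_small, refs)
  a2 <- annotate_library(rev_lib, refs)
  a2 <- a2[match(a1$sequence, a2$sequence), ]
  rownames(a2) <- NULL
  expect_equal(a1$class, a2$class)
  expect_equal(a1$parent_id, a2$parent_id)
  expect_equal(a1$tsrna_category, a2$tsrna_category)
})

test_that("RPM normalizes mapped features to one million per sample", {
  counts <- matrix(c(1, 3, 0, 4), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  rpm <- compute_rpm(counts)
  expect_equal(rpm[, "s1"], c(a = 250000, b = 750000))
  expect_equal(compute_rpm(matrix(5, 1, 1))[1, 1], 1e6)
  expect_error(compute_rpm(matrix(0, 2, 1)), "zero mapped")
})

test_that("count matrix partitions library counts and genome rate is weighted", {
  refs <- fixture_refs()
  lib <- fixture_libs()[[1]]
  ann <- annotate_library(lib, refs)
  # conservation: annotated counts equal retained read counts
  expect_equal(sum(ann$count),
               sum(lib$reads$count) - attr(ann, "n_length_dropped"))
  cm <- build_count_matrix(list(S1 = ann), by = "class")
  expect_equal(sum(cm$counts), sum(ann$count))
  mapped <- cm$feature_class[rownames(cm$rpm)] != "unmapped"
  expect_lt(abs(sum(cm$rpm[mapped, 1]) - 1e6), 1e-6)

  # half the total count bacterial-only -> host match rate 0.5
  bac <- substr(refs$bacterial_genomes[[1]], 50, 80)
  hostread <- refs$mirnas[[2]]
  lib2 <- list(reads = data.frame(sequence = c(hostread, bac),
                                  count = c(10L, 10L)))
  expect_equal(genome_match_rate(lib2, refs$host_genome), 0.5)
  expect_error(genome_match_rate(list(reads = NULL), refs$host_genome),
               "empty")
})

test_that("length histogram is count-weighted and conserves totals", {
  lib <- list(reads = data.frame(sequence = c(strrep("A", 20), strrep("C", 31)),
                                 count = c(7L, 2L)))
  h <- length_distribution(lib)
  expect_equal(unname(h["20"]), 7L)
  expect_equal(unname(h["31"]), 2L)
  expect_equal(sum(h), 9L)
  empty <- length_distribution(lib, annotation = data.frame(
    sequence = character(0), class = character(0)), class_filter = "miRNA")
  expect_true(all(empty == 0))
})
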