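# Host-unmapped extraction, abundance filtering, size factors, the NB Wald
# test and taxonomy/composition summaries.

test_that("host-only libraries yield an empty exogenous table", {
  refs <- fixture_refs()
  lib <- list(sample_id = "s1",
              reads = data.frame(sequence = unname(refs$mirnas[1:3]),
                                 count = c(5L, 2L, 9L)))
  exo <- extract_unmapped(list(lib), refs$host_genome)
  expect_equal(nrow(exo), 0)
})

test_that("planted bacterial fragments are all extracted with correct counts", {
  refs <- fixture_refs()
  libs <- fixture_libs()
  uni <- attr(libs, "universe")
  bact <- uni$sequence[uni$class == "bacterial"]
  exo <- extract_unmapped(libs, refs$host_genome)
  present <- vapply(libs, function(l) any(l$reads$sequence %in% bact),
                    logical(1))
  expect_true(any(present))
  expect_true(all(exo$fragment %in% bact))
  # spot-check counts against a per-read oracle for one sample
  s <- libs[[1]]
  for (fr in head(exo$fragment, 5)) {
    want <- sum(s$reads$count[s$reads$sequence == fr])
    expect_equal(exo[[s$sample_id]][exo$fragment == fr], want)
  }
})

test_that("low-abundance filter removes strictly below the threshold", {
  tab <- data.frame(fragment = c("a", "b", "c"),
                    s1 = c(999, 1000, 1001),
                    total = c(999, 1000, 1001))
  out <- filter_low_abundance(tab)
  expect_setequal(out$fragment, c("b", "c"))
  expect_equal(attr(out, "removed")$fragment, "a")
  empty <- filter_low_abundance(tab[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(out) + nrow(attr(out, "removed")), nrow(tab))
})

test_that("median-of-ratios size factors match the closed form", {
  cnt <- matrix(c(10, 20, 30, 20, 40, 60), 3, 2)
  s <- size_factors_median_ratio(cnt)
  expect_equal(s, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  ident <- size_factors_median_ratio(matrix(c(5, 7, 5, 7), 2, 2))
  expect_equal(ident, c(1, 1))
  set.seed(2)
  r <- matrix(rpois(60, 50) + 1, 10, 6)
  expect_equal(exp(mean(log(size_factors_median_ratio(r)))), 1)
  expect_error(size_factors_median_ratio(matrix(c(0, 1, 1, 0), 2, 2)),
               "nonzero")
})

test_that("identical groups give fold change one and p one", {
  cnt <- matrix(rep(c(40, 80, 120), each = 6), 3, 6, byrow = TRUE,
                dimnames = list(paste0("f", 1:3), paste0("s", 1:6)))
  de <- nb_wald_test(cnt, rep(c("a", "b"), each = 3))
  expect_equal(de$log2fc, rep(0, 3))
  expect_equal(de$p, rep(1, 3))
  expect_false(any(de$significant))
  expect_error(nb_wald_test(cnt, c("a", "a", "a", "a", "a", "b")),
               "2 samples")
})

test_that("the NB test controls the Poisson null and detects a planted shift", {
  set.seed(3)
  disc <- 0
  for (s in 1:20) {
    cnt <- matrix(rpois(200 * 10, 100), 200, 10,
                  dimnames = list(paste0("f", 1:200), paste0("s", 1:10)))
    de <- nb_wald_test(cnt, rep(c("a", "b"), each = 5))
    disc <- disc + sum(de$significant)
  }
  expect_equal(disc, 0)
  det <- 0
  for (s in 1:20) {
    cnt <- rbind(matrix(rpois(50 * 10, 300), 50, 10),
                 matrix(c(rpois(5, 500), rpois(5, 4000)), 1, 10,
                        byrow = TRUE))
    dimnames(cnt) <- list(paste0("f", 1:51), paste0("s", 1:10))
    de <- nb_wald_test(cnt, rep(c("a", "b"), each = 5))
    det <- det + de$significant[51]
  }
  expect_gte(det, 19)
})

test_that("all-zero groups are floored, not errors", {
  cnt <- rbind(f1 = c(0, 0, 0, 50, 60, 40),
               f2 = c(30, 35, 25, 30, 35, 25))
  colnames(cnt) <- paste0("s", 1:6)
  de <- nb_wald_test(cnt, rep(c("a", "b"), each = 3))
  expect_true(all(is.finite(de$log2fc)))
  expect_gt(de$log2fc[de$fragment == "f1"], 0)
})

test_that("taxonomy is exact, order-independent and flags ambiguity", {
  refs <- fixture_refs()
  g <- refs$bacterial_genomes
  f_sa <- substr(g[["Staphylococcus_aureus"]], 200, 225)
  f_none <- strrep("AC", 13)
  tax <- assign_taxonomy(c(f_sa, f_none), g)
  expect_equal(tax$species, c("Staphylococcus_aureus", "unassigned"))
  # a fragment present in two genomes is ambiguous
  g2 <- c(g, dup = paste0("TTTT", f_sa, "GGGG"))
  tax2 <- assign_taxonomy(f_sa, g2)
  expect_equal(tax2$species, "ambiguous")
  # order independence
  tax3 <- assign_taxonomy(rev(c(f_sa, f_none)), g)
  expect_equal(rev(tax3$species), tax$species)
})

test_that("species composition reproduces a planted read-weight mixture", {
  refs <- fixture_refs()
  libs <- fixture_libs()
  cfg <- fixture_cfg()
  exo <- extract_unmapped(libs, refs$host_genome)
  tax <- assign_taxonomy(exo$fragment, refs$bacterial_genomes)
  comp <- species_composition(exo, tax)
  expect_equal(sum(comp$percent), 100)
  expect_equal(comp$species[1], "Staphylococcus_aureus")
  # dominant species within 3 multinomial SDs of its planted weight (the
  # 30 h spike redistributes some mass between species)
  n_reads <- sum(exo$total)
  p <- cfg$species_mix[["Staphylococcus_aureus"]]
  sd3 <- 3 * sqrt(p * (1 - p) / n_reads) * 100
  expect_lt(abs(comp$percent[1] - 100 * p), sd3 + 6)
})

test_that("species match trajectory is flat-zero without bacterial reads", {
  refs <- fixture_refs()
  lib <- list(sample_id = "s", timepoint = 0,
              reads = data.frame(sequence = unname(refs$mirnas[1:4]),
                                 count = rep(10L, 4)))
  traj <- species_match_trajectory(list(lib, lib),
                                   refs$bacterial_genomes[1])
  expect_equal(traj$mean_rate, 0)
  expect_true(all(traj$mean_rate >= 0 & traj$mean_rate <= 1))
})

test_that("planted bacterial trajectory rises towards the late time points", {
  refs <- fixture_refs()
  libs <- fixture_libs()
  traj <- species_match_trajectory(
    libs, refs$bacterial_genomes["Staphylococcus_aureus"])
  expect_equal(nrow(traj), 6)
  expect_gt(traj$mean_rate[6], traj$mean_rate[1])
  expect_true(all(traj$mean_rate >= 0 & traj$mean_rate <= 1))
})
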