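# Generator determinism, invariants and planted-parameter recovery.

test_that("reference generation is deterministic and byte-identical on export", {
  r1 <- generate_toy_references(seed = 3, sizes = small_ref_sizes())
  r2 <- generate_toy_references(seed = 3, sizes = small_ref_sizes())
  expect_identical(r1, r2)
  d1 <- file.path(tempdir(), "fa1"); d2 <- file.path(tempdir(), "fa2")
  write_reference_fasta(r1, d1)
  write_reference_fasta(r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  rt <- read_reference_fasta(d1)
  expect_equal(rt$mature_trnas, r1$mature_trnas)
  expect_equal(rt$pre_trnas$intron_start, r1$pre_trnas$intron_start)
  expect_equal(rt$bacterial_cds$category, r1$bacterial_cds$category)
})

test_that("bacterial genomes share no 15-mer with the host genome", {
  refs <- fixture_refs()
  # exhaustive k-mer set intersection, built inline
  kmers <- function(s, k) {
    n <- nchar(s)
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  host_k <- unique(unlist(lapply(refs$host_genome, kmers, k = 15)))
  for (g in refs$bacterial_genomes) {
    expect_length(intersect(kmers(g, 15), host_k), 0)
  }
  expect_true(validate_reference_set(refs))
})

test_that("degenerate reference requests error", {
  expect_error(generate_toy_references(seed = 1, sizes = list(n_rrnas = 0)),
               "n_rrnas")
  expect_error(
    generate_toy_references(seed = 1,
                            sizes = list(rrna_lengths = c(100, 100, 200, 300))),
    "distinct")
})

test_that("libraries conserve depth and embed every endogenous read", {
  libs <- fixture_libs()
  cfg <- fixture_cfg()
  refs <- fixture_refs()
  expect_length(libs, length(cfg$timepoints_h) * cfg$replicates)
  for (lib in libs[c(1, 15, 30)]) {
    expect_equal(sum(lib$reads$count), cfg$depth)
  }
  uni <- attr(libs, "universe")
  endo <- uni$class != "bacterial"
  hit <- pmiclock:::.match_any_cpp(uni$sequence[endo],
                                   unname(refs$host_genome), 0L)
  expect_true(all(hit))
})

test_that("flat zero-noise dynamics give equal class RPM across time", {
  flat <- fixture_cfg()$class_dynamics
  flat[, ] <- 1
  cfg <- sim_config(seed = 4, depth = 2e5, noise_cv = 0,
                    class_dynamics = flat,
                    exo_spike = list(frac = rep(0.004, 6), spike_mult = 1,
                                     spike_frac = 0.4))
  libs <- generate_srna_libraries(fixture_refs(), cfg)
  uni <- attr(libs, "universe")
  cls_of <- setNames(uni$class, uni$sequence)
  class_rpm <- sapply(libs, function(l) {
    cl <- cls_of[l$reads$sequence]
    tot <- tapply(l$reads$count, cl, sum)
    tot[["tsRNA"]] / sum(l$reads$count)
  })
  # multinomial sampling noise only: relative spread is small
  expect_lt(max(class_rpm) / min(class_rpm), 1.10)
})

test_that("planted tsRNA trajectory is recovered in RPM ratios", {
  libs <- fixture_libs()
  uni <- attr(libs, "universe")
  cls_of <- setNames(uni$class, uni$sequence)
  rpm_ts <- vapply(libs, function(l) {
    cl <- cls_of[l$reads$sequence]
    sum(l$reads$count[cl == "tsRNA"]) / sum(l$reads$count) * 1e6
  }, numeric(1))
  tp <- vapply(libs, `[[`, numeric(1), "timepoint")
  ratio <- mean(rpm_ts[tp == 12]) / mean(rpm_ts[tp == 0])
  expect_gt(ratio, 1.5 * 0.9)
  expect_lt(ratio, 1.5 * 1.1)
})

test_that("zero exogenous spike leaves no bacterial-matching fragments", {
  cfg <- sim_config(seed = 9, depth = 30000,
                    exo_spike = list(frac = rep(0, 6), spike_mult = 1,
                                     spike_frac = 0.4))
  refs <- fixture_refs()
  libs <- generate_srna_libraries(refs, cfg)
  exo <- extract_unmapped(libs, refs$host_genome)
  expect_equal(nrow(exo), 0)
})

test_that("RIN model is a clipped noiseless line when sd = 0", {
  pars <- default_rin_params()
  pars$sd[] <- 0
  pars$intercept[pars$organ == "heart"] <- 9
  pars$slope[pars$organ == "heart"] <- 0.15
  cfg <- sim_config(seed = 2, rin_params = pars)
  rin <- generate_rin_table(cfg)
  h48 <- rin$rin[rin$organ == "heart" & rin$timepoint_h == 48]
  expect_equal(unique(h48), max(1, 9 - 0.15 * 48))
  expect_true(all(rin$rin >= 1 & rin$rin <= 10))
})

test_that("invalid RIN parameterizations are rejected", {
  pars <- default_rin_params()
  pars$intercept[1] <- 12
  expect_error(sim_config(rin_params = pars), "\\[1, 10\\]")
  pars <- default_rin_params()
  pars$slope[1] <- -0.1
  expect_error(sim_config(rin_params = pars), "slope")
})

test_that("per-organ OLS recovers planted RIN slopes within 2 SE", {
  cfg <- sim_config(seed = 21)
  rin <- generate_rin_table(cfg)
  fits <- fit_linear_per_organ(rin)
  pars <- cfg$rin_params
  for (i in seq_len(nrow(fits))) {
    planted <- -pars$slope[pars$organ == fits$organ[i]]
    # clipping at RIN = 1 flattens the tail for fast-degrading organs;
    # allow the planted slope to sit within 2 SE of the estimate
    expect_lt(abs(fits$slope[i] - planted), 2 * fits$slope_se[i] + 0.02)
  }
  expect_equal(fits$slope[fits$organ == "brain"],
               max(fits$slope))  # slowest decline (least negative)
})

test_that("delta-Ct generator is a noiseless line at sd = 0 and errors sensibly", {
  pars <- default_deltact_params()
  pars$sd[] <- 0
  pars$slope[1] <- 0.002
  cfg <- sim_config(seed = 5, deltact_params = pars)
  d <- generate_deltact_matrix(cfg)
  f <- pars$feature[1]
  fit <- lm(d$x[, f] ~ d$pmi_min)
  expect_equal(unname(coef(fit)[2]), 0.002, tolerance = 1e-9)
  # delta-Ct at PMI 1000 exceeds delta-Ct at PMI 0 by exactly 2 cycles
  expect_equal(unname(pars$intercept[1] + 0.002 * 1000 -
                        pars$intercept[1]), 2)

  # planted set is derived from the slope column, so it can never exceed
  # the feature count; degenerate designs are rejected instead
  expect_error(generate_deltact_matrix(sim_config(n_animals = 1)),
               "at least two animals")
})

test_that("planted biomarker slopes have positive sign in least squares", {
  hits <- 0
  for (s in 1:20) {
    d <- generate_deltact_matrix(sim_config(seed = s))
    ok <- all(vapply(d$biomarkers, function(f) {
      unname(coef(lm(d$x[, f] ~ d$pmi_min))[2]) > 0
    }, logical(1)))
    hits <- hits + ok
  }
  expect_gte(hits, 19)
})

test_that("context score table satisfies its fixture guarantees", {
  refs <- fixture_refs()
  ctx <- generate_context_table(refs, fixture_cfg())
  expect_true(all(ctx$context_score <= 0))
  expect_true(all(ctx$percentile >= 0 & ctx$percentile <= 100))
  expect_gte(sum(ctx$context_score <= -0.2 & ctx$percentile >= 90), 1)
  expect_gte(sum(ctx$context_score > -0.2), 1)
  expect_gte(sum(ctx$percentile < 90), 1)
  expect_identical(ctx, generate_context_table(refs, fixture_cfg()))
})

test_that("library TSV round trip preserves reads and metadata", {
  libs <- fixture_libs()[1:2]
  d <- file.path(tempdir(), "libio")
  write_library_tsv(libs, d)
  back <- read_library_tsv(d)
  expect_equal(back[[1]]$reads$sequence, libs[[1]]$reads$sequence)
  expect_equal(back[[2]]$reads$count, libs[[2]]$reads$count)
  expect_equal(back[[1]]$timepoint, libs[[1]]$timepoint)
})
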