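# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

small_ref_sizes <- function() {
  list(n_trnas = 8, n_rrnas = 4, rrna_lengths = c(80, 110, 300, 500),
       n_yrnas = 3, n_mirnas = 24, n_pirnas = 16, n_snornas = 6,
       bact_genome_len = 1200, n_cds = 6, host_filler = 2500)
}

fixture_refs <- function() {
  if (is.null(.fixture_env$refs)) {
    .fixture_env$refs <- generate_toy_references(seed = 11,
                                                 sizes = small_ref_sizes())
  }
  .fixture_env$refs
}

fixture_cfg <- function() {
  sim_config(seed = 11, depth = 50000)
}

fixture_libs <- function() {
  if (is.null(.fixture_env$libs)) {
    .fixture_env$libs <- generate_srna_libraries(fixture_refs(), fixture_cfg())
  }
  .fixture_env$libs
}

# adjusted Rand index between two hard labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}
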