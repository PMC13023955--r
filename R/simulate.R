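# Synthetic-data generators. These emulate the statistical structure of a
# postmortem cardiac small-RNA time-course study -- declining RIN across
# organs, class-level sncRNA trajectories, planted qPCR biomarkers, and a
# late bacterial fragment spike -- so that every downstream stage of the
# pipeline can be exercised and tested without external data.

RIN_ORGANS <- c("lung", "liver", "muscle", "brain", "heart", "testis",
                "spleen", "kidney")

SNC_CLASSES <- c("rsRNA", "mt-tsRNA", "tsRNA", "miRNA", "piRNA", "ysRNA",
                 "snoRNA", "other_ncRNA")

default_class_dynamics <- function() {
  # multiplicative class trajectories over 0/6/12/18/24/30 h, anchored to
  # the reported cardiac time-course: tsRNA +50% at 12 h and +76% at 18 h,
  # piRNA rising ~1.33x from 12 h on, ysRNA halving by 30 h, rsRNA stable.
  m <- rbind(
    "rsRNA"       = c(1, 1, 1, 1, 1, 1),
    "mt-tsRNA"    = c(1, 1.20, 1.45, 1.70, 1.70, 1.70),
    "tsRNA"       = c(1, 1.25, 1.50, 1.76, 1.76, 1.76),
    "miRNA"       = c(1, 1, 1, 1, 1, 1),
    "piRNA"       = c(1, 1, 1.05, 1.15, 1.25, 1.33),
    "ysRNA"       = c(1, 0.95, 0.85, 0.72, 0.60, 0.50),
    "snoRNA"      = c(1, 1, 1, 1, 1, 1),
    "other_ncRNA" = c(1, 1, 1, 1, 1, 1))
  colnames(m) <- c("0", "6", "12", "18", "24", "30")
  m
}

default_class_share <- function() {
  # baseline composition of mapped reads (t = 0): rRNA-derived fragments
  # dominate, tsRNA ~3.8%, piRNA < 0.1%, miRNA/snoRNA < 1% each.
  c("rsRNA" = 0.60, "mt-tsRNA" = 0.20, "tsRNA" = 0.038, "miRNA" = 0.030,
    "piRNA" = 0.00075, "ysRNA" = 0.010, "snoRNA" = 0.005,
    "other_ncRNA" = 0.10)
}

default_rin_params <- function() {
  # per-organ linear decline (RIN units / h); the brain declines slowest,
  # the heart has the largest slope-to-noise ratio (tightest clock).
  data.frame(
    organ = RIN_ORGANS,
    intercept = c(8.6, 8.2, 8.9, 9.3, 9.2, 9.0, 8.4, 8.7),
    slope = c(0.115, 0.125, 0.135, 0.040, 0.150, 0.140, 0.130, 0.135),
    sd = c(0.75, 0.80, 0.55, 0.50, 0.28, 0.50, 0.60, 0.60),
    stringsAsFactors = FALSE)
}

default_deltact_params <- function() {
  # 20-feature qPCR panel (16 tsRNAs + 4 piRNAs), 7 planted PMI-informative
  # biomarkers (4 tsRNAs + 3 piRNAs) whose delta-Ct rises with PMI, i.e.
  # 2^(-dCt) expression declines. Slopes in cycles/min, noise in cycles.
  aa <- c("Gly", "Glu", "Val", "Lys", "Asp", "His", "Ala", "Leu", "Ser",
          "Arg", "Cys", "Met", "Pro", "Thr", "Ile", "Phe")
  ts <- sprintf("tsRNA-%s-%02d", aa, seq_along(aa))
  pi <- sprintf("piR-mmu-%05d", c(34076, 67900, 12238, 50518))
  feats <- c(ts, pi)
  bio <- c(ts[c(1, 4, 7, 10)], pi[1:3])
  slopes <- setNames(rep(0, length(feats)), feats)
  slopes[bio] <- c(0.0022, 0.0018, 0.0015, 0.0012, 0.0025, 0.0020, 0.0014)
  data.frame(
    feature = feats,
    class = rep(c("tsRNA", "piRNA"), c(length(ts), length(pi))),
    intercept = seq(3, 9.5, length.out = length(feats)),
    slope = unname(slopes),
    sd = rep(0.8, length(feats)),
    stringsAsFactors = FALSE)
}

default_exo_spike <- function() {
  # bacterial read fraction per time point, plus a late spike: a subset of
  # fragments (spike_frac of each species) is upregulated spike_mult-fold
  # at 30 h, emulating the burst of microbe-specific fragments while most
  # of the community signal stays near-flat.
  list(frac = c(0.0036, 0.0042, 0.0043, 0.0044, 0.0045, 0.0045),
       spike_mult = 6, spike_frac = 0.4)
}

default_species_mix <- function() {
  c("Staphylococcus_aureus" = 0.77, "Klebsiella_pneumoniae" = 0.129,
    "uncultured_bacterium" = 0.099, "Vibrio_sp" = 0.002)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults encode the
#' study conditions the generators emulate: 6 postmortem time points
#' (0-30 h) with 5 replicates for sequencing, 8 organs x 8 time points
#' (0-48 h) x 6 replicates for RIN, 71 animals at uniform random PMIs up to
#' 1470 min for the 20-feature qPCR panel with 7 planted biomarkers, and
#' the printed class-level trajectory multipliers.
#'
#' @param seed integer master seed; all generator randomness derives from
#'   it.
#' @param timepoints_h sequencing time points in hours.
#' @param replicates sequencing replicates per time point.
#' @param depth collapsed reads per library (total count, conserved
#'   exactly).
#' @param noise_cv lognormal coefficient of variation of per-fragment,
#'   per-sample abundance noise (0 disables noise).
#' @param class_dynamics class x timepoint multiplier matrix.
#' @param class_share baseline class composition at 0 h.
#' @param rin_params per-organ intercept/slope/sd table.
#' @param rin_timepoints_h,rin_replicates RIN design.
#' @param deltact_params qPCR panel feature table.
#' @param n_animals,pmi_max_min qPCR design: animals and maximal PMI (min).
#' @param expression_sign `"negative"` (default): planted biomarker
#'   expression `2^(-dCt)` declines with PMI (positive dCt slope);
#'   `"positive"` flips the convention.
#' @param exo_spike list with `frac` (bacterial read fraction per time
#'   point), `spike_mult`, `spike_frac`.
#' @param species_mix read-weight proportions per bacterial species
#'   (normalized internally).
#' @param mirna_cluster_peaks peak time point index (1..T) per temporal
#'   archetype used for miRNA cluster structure.
#' @return a list of class `pmi_sim_config`.
#' @export
sim_config <- function(seed = 1,
                       timepoints_h = c(0, 6, 12, 18, 24, 30),
                       replicates = 5,
                       depth = 200000,
                       noise_cv = 0.15,
                       class_dynamics = default_class_dynamics(),
                       class_share = default_class_share(),
                       rin_params = default_rin_params(),
                       rin_timepoints_h = seq(0, 48, by = 6),
                       rin_replicates = 6,
                       deltact_params = default_deltact_params(),
                       n_animals = 71,
                       pmi_max_min = 1470,
                       expression_sign = c("negative", "positive"),
                       exo_spike = default_exo_spike(),
                       species_mix = default_species_mix(),
                       mirna_cluster_peaks = 1:6) {
  expression_sign <- match.arg(expression_sign)
  stop_if_not_number(seed, "seed")
  stop_if_not_number(noise_cv, "noise_cv", lo = 0)
  stop_if_not_number(depth, "depth", lo = 1)
  if (any(class_dynamics < 0)) stop("negative trajectory multipliers",
                                    call. = FALSE)
  if (any(rin_params$slope < 0)) stop("RIN slopes must be >= 0 (decline rate)",
                                      call. = FALSE)
  if (any(rin_params$intercept < 1 | rin_params$intercept > 10)) {
    stop("RIN intercepts must lie in [1, 10]", call. = FALSE)
  }
  if (any(rin_params$sd < 0) || any(deltact_params$sd < 0)) {
    stop("noise sds must be >= 0", call. = FALSE)
  }
  species_mix <- species_mix / sum(species_mix)
  structure(list(
    seed = as.integer(seed), timepoints_h = timepoints_h,
    replicates = replicates, depth = depth, noise_cv = noise_cv,
    class_dynamics = class_dynamics, class_share = class_share,
    rin_params = rin_params, rin_timepoints_h = rin_timepoints_h,
    rin_replicates = rin_replicates, deltact_params = deltact_params,
    n_animals = n_animals, pmi_max_min = pmi_max_min,
    expression_sign = expression_sign, exo_spike = exo_spike,
    species_mix = species_mix, mirna_cluster_peaks = mirna_cluster_peaks),
    class = "pmi_sim_config")
}

default_ref_sizes <- function() {
  list(n_trnas = 16, n_rrnas = 4, rrna_lengths = c(121, 156, 1100, 1869),
       n_yrnas = 4, n_mirnas = 60, n_pirnas = 40, n_snornas = 12,
       bact_genome_len = 2500, n_cds = 8, host_filler = 6000)
}

#' Generate a toy reference set
#'
#' Builds a self-consistent toy reference universe: host sncRNA classes
#' (pre-tRNAs with introns and at least one histidine tRNA, rRNAs of
#' strictly distinct lengths, YRNAs, miRNAs, piRNAs, snoRNAs), a host
#' "genome" in which every endogenous sequence (including the constructed
#' mature tRNAs) is embedded verbatim, and bacterial genomes plus
#' categorized CDS that share no 15-mer with the host genome, so exogenous
#' extraction is unambiguous.
#'
#' @param seed integer seed.
#' @param sizes list of per-class sizes (see `default_ref_sizes()`).
#' @return object of class `pmi_refs`.
#' @export
generate_toy_references <- function(seed = 1, sizes = default_ref_sizes()) {
  sz <- utils::modifyList(default_ref_sizes(), sizes)
  for (nm in c("n_trnas", "n_rrnas", "n_yrnas", "n_mirnas", "n_pirnas",
               "n_snornas", "n_cds")) {
    if (sz[[nm]] < 1) stop(sprintf("sizes$%s must be >= 1", nm), call. = FALSE)
  }
  if (length(sz$rrna_lengths) != sz$n_rrnas ||
      anyDuplicated(sz$rrna_lengths)) {
    stop("rrna_lengths must give n_rrnas pairwise distinct lengths",
         call. = FALSE)
  }
  with_seed(derive_seed(seed, "references"), {
    aa_pool <- c("His", "Gly", "Glu", "Val", "Lys", "Asp", "Ala", "Leu",
                 "Ser", "Arg", "Cys", "Met", "Pro", "Thr", "Ile", "Phe")
    n_tr <- sz$n_trnas
    aa <- rep_len(aa_pool, n_tr)  # guarantees at least one His
    body_len <- sample(70:82, n_tr, replace = TRUE)
    seqs <- random_dna(n_tr, 1)
    pre <- character(n_tr)
    intron_start <- rep(NA_integer_, n_tr)
    intron_end <- rep(NA_integer_, n_tr)
    with_intron <- seq_len(n_tr) %in% sample(n_tr, max(1, n_tr %/% 5))
    for (i in seq_len(n_tr)) {
      s <- random_dna(1, body_len[i])
      if (with_intron[i]) {
        ilen <- sample(10:20, 1)
        at <- sample(30:45, 1)
        s <- paste0(substr(s, 1, at - 1), random_dna(1, ilen),
                    substr(s, at, nchar(s)))
        intron_start[i] <- at
        intron_end[i] <- at + ilen - 1
      }
      # 3' trailer so the pre-tRNA 3' end differs from the mature end
      pre[i] <- paste0(s, random_dna(1, sample(8:14, 1)))
    }
    mito <- seq_len(n_tr) %in% sample(n_tr, max(1, n_tr %/% 8))
    pre_trnas <- data.frame(
      id = sprintf("tRNA-%s-%02d%s", aa, seq_len(n_tr),
                   ifelse(mito, "-mt", "")),
      seq = pre, intron_start = intron_start, intron_end = intron_end,
      aa = aa, mito = mito, stringsAsFactors = FALSE)
    mature <- build_mature_trnas(pre_trnas)

    rrnas <- setNames(random_dna(sz$n_rrnas, 1), NULL)
    rrnas <- vapply(seq_len(sz$n_rrnas),
                    function(i) random_dna(1, sz$rrna_lengths[i]),
                    character(1))
    names(rrnas) <- sprintf("rRNA-%s", c("5S", "5.8S", "18S", "28S",
                                         paste0("x", seq_len(max(0, sz$n_rrnas - 4))))[seq_len(sz$n_rrnas)])
    yrnas <- setNames(vapply(seq_len(sz$n_yrnas),
                             function(i) random_dna(1, sample(95:105, 1)),
                             character(1)),
                      sprintf("YRNA-%d", seq_len(sz$n_yrnas)))
    mirnas <- setNames(vapply(seq_len(sz$n_mirnas),
                              function(i) random_dna(1, sample(21:23, 1)),
                              character(1)),
                       sprintf("miR-%03d", seq_len(sz$n_mirnas)))
    pirnas <- setNames(vapply(seq_len(sz$n_pirnas),
                              function(i) random_dna(1, sample(26:31, 1)),
                              character(1)),
                       sprintf("piR-%05d", seq_len(sz$n_pirnas)))
    snornas <- setNames(vapply(seq_len(sz$n_snornas),
                               function(i) random_dna(1, sample(60:80, 1)),
                               character(1)),
                        sprintf("snoRNA-%02d", seq_len(sz$n_snornas)))

    # host genome: random filler with every endogenous sequence embedded
    embed <- c(pre_trnas$seq, unname(mature), unname(rrnas), unname(yrnas),
               unname(mirnas), unname(pirnas), unname(snornas))
    n_block <- length(embed) + 1
    fill_len <- pmax(30, stats::rmultinom(1, sz$host_filler, rep(1, n_block))[, 1])
    filler <- vapply(fill_len, function(L) random_dna(1, L), character(1))
    host <- paste0(paste0(filler[seq_along(embed)], embed, collapse = ""),
                   filler[n_block])
    host_genome <- c(chr1 = host)
    filler_blocks <- filler  # retained so genomic-only fragments can be drawn

    host_kmers <- kmer_set(host_genome, 15)
    species <- names(default_species_mix())
    bacterial_genomes <- character(0)
    for (sp in species) {
      for (try in 1:50) {
        g <- random_dna(1, sz$bact_genome_len)
        if (!any(kmer_set(g, 15) %in% host_kmers)) break
        g <- NA_character_
      }
      if (is.na(g)) stop("could not generate a host-disjoint bacterial genome",
                         call. = FALSE)
      bacterial_genomes[sp] <- g
    }
    categories <- c("metabolic enzyme", "virulence factor",
                    "DNA/RNA processing and translation", "other")
    cds_list <- lapply(species, function(sp) {
      g <- bacterial_genomes[[sp]]
      starts <- sort(sample(seq_len(nchar(g) - 320), sz$n_cds))
      lens <- sample(seq(120, 300, by = 3), sz$n_cds, replace = TRUE)
      data.frame(
        id = sprintf("%s_cds%02d", sp, seq_len(sz$n_cds)),
        species = sp,
        category = sample(categories, sz$n_cds, replace = TRUE,
                          prob = c(0.4, 0.2, 0.25, 0.15)),
        seq = substring(g, starts, pmin(nchar(g), starts + lens - 1)),
        stringsAsFactors = FALSE)
    })
    bacterial_cds <- do.call(rbind, cds_list)

    structure(list(
      host_genome = host_genome, filler_blocks = filler_blocks,
      pre_trnas = pre_trnas, mature_trnas = mature, rrnas = rrnas,
      yrnas = yrnas, mirnas = mirnas, pirnas = pirnas, snornas = snornas,
      bacterial_genomes = bacterial_genomes, bacterial_cds = bacterial_cds),
      class = "pmi_refs")
  })
}

#' Check the internal invariants of a reference set
#'
#' @param refs a `pmi_refs` object.
#' @return invisibly `TRUE`; stops with a message when an invariant fails.
#' @export
validate_reference_set <- function(refs) {
  all_seq <- c(refs$host_genome, refs$pre_trnas$seq, refs$mature_trnas,
               refs$rrnas, refs$yrnas, refs$mirnas, refs$pirnas,
               refs$snornas, refs$bacterial_genomes, refs$bacterial_cds$seq)
  assert_alphabet(all_seq, "reference set")
  if (anyDuplicated(nchar(refs$rrnas))) {
    stop("rRNA lengths are not pairwise distinct", call. = FALSE)
  }
  endo <- c(refs$pre_trnas$seq, refs$mature_trnas, refs$rrnas, refs$yrnas,
            refs$mirnas, refs$pirnas, refs$snornas)
  embedded <- .match_any_cpp(unname(endo), unname(refs$host_genome), 0L)
  if (!all(embedded)) {
    stop("an endogenous reference sequence is not embedded in the host genome",
         call. = FALSE)
  }
  hk <- kmer_set(refs$host_genome, 15)
  bk <- kmer_set(refs$bacterial_genomes, 15)
  if (any(bk %in% hk)) {
    stop("bacterial genomes share a 15-mer with the host genome", call. = FALSE)
  }
  invisible(TRUE)
}

# Build the deterministic fragment universe for library simulation:
# data.frame(sequence, feature_id, class, base_weight, peak (miRNA
# archetype), species, spike).
build_fragment_universe <- function(refs, cfg) {
  frag <- function(seq, feature_id, class, species = NA_character_,
                   spike = FALSE) {
    data.frame(sequence = seq, feature_id = feature_id, class = class,
               species = species, spike = spike, stringsAsFactors = FALSE)
  }
  sub_rand <- function(s, len) {
    len <- min(len, nchar(s))
    at <- sample(max(1, nchar(s) - len + 1), 1)
    substr(s, at, at + len - 1)
  }
  rows <- list()
  # tsRNA fragments per tRNA: 5', 3'-CCA, internal, pre-tRNA 3'
  for (i in seq_len(nrow(refs$pre_trnas))) {
    id <- refs$pre_trnas$id[i]
    m <- refs$mature_trnas[[id]]
    p <- refs$pre_trnas$seq[i]
    cl <- if (isTRUE(refs$pre_trnas$mito[i])) "mt-tsRNA" else "tsRNA"
    l5 <- sample(16:28, 1); l3 <- sample(18:24, 1); li <- sample(16:24, 1)
    rows[[length(rows) + 1]] <- frag(
      c(substr(m, 1, l5),
        substr(m, nchar(m) - l3 + 1, nchar(m)),
        substr(m, 10, 9 + li),
        substr(p, nchar(p) - sample(18:22, 1) + 1, nchar(p))),
      id, cl)
  }
  for (id in names(refs$rrnas)) {
    s <- refs$rrnas[[id]]
    n_frag <- 6
    rows[[length(rows) + 1]] <- frag(
      vapply(seq_len(n_frag), function(k) sub_rand(s, sample(18:40, 1)),
             character(1)), id, "rsRNA")
  }
  for (id in names(refs$yrnas)) {
    rows[[length(rows) + 1]] <- frag(
      vapply(1:3, function(k) sub_rand(refs$yrnas[[id]], sample(20:34, 1)),
             character(1)), id, "ysRNA")
  }
  rows[[length(rows) + 1]] <- frag(unname(refs$mirnas), names(refs$mirnas),
                                   "miRNA")
  rows[[length(rows) + 1]] <- frag(unname(refs$pirnas), names(refs$pirnas),
                                   "piRNA")
  for (id in names(refs$snornas)) {
    rows[[length(rows) + 1]] <- frag(
      vapply(1:2, function(k) sub_rand(refs$snornas[[id]], sample(18:32, 1)),
             character(1)), id, "snoRNA")
  }
  # genomic-only fragments drawn from host filler blocks
  big <- refs$filler_blocks[nchar(refs$filler_blocks) >= 40]
  n_gen <- min(30, length(big))
  rows[[length(rows) + 1]] <- frag(
    vapply(sample(big, n_gen), function(s) sub_rand(s, sample(18:35, 1)),
           character(1)),
    sprintf("genomic-%02d", seq_len(n_gen)), "other_ncRNA")
  # bacterial fragments
  n_bact <- c(8, 3, 3, 2)[seq_along(refs$bacterial_genomes)]
  sp_names <- names(refs$bacterial_genomes)
  for (k in seq_along(sp_names)) {
    g <- refs$bacterial_genomes[[k]]
    nk <- n_bact[k]
    spike <- seq_len(nk) <= max(1, round(nk * cfg$exo_spike$spike_frac))
    rows[[length(rows) + 1]] <- frag(
      vapply(seq_len(nk), function(j) sub_rand(g, sample(20:35, 1)),
             character(1)),
      sprintf("%s_frag%02d", sp_names[k], seq_len(nk)), "bacterial",
      species = sp_names[k], spike = spike)
  }
  uni <- do.call(rbind, rows)
  uni <- uni[!duplicated(uni$sequence), , drop = FALSE]
  rownames(uni) <- NULL

  # base weights: lognormal within class, scaled to the class share
  w <- rlnorm(nrow(uni), 0, 1)
  share <- cfg$class_share
  for (cl in names(share)) {
    in_cl <- uni$class == cl
    if (any(in_cl)) w[in_cl] <- w[in_cl] / sum(w[in_cl]) * share[[cl]]
  }
  for (sp in names(cfg$species_mix)) {
    in_sp <- !is.na(uni$species) & uni$species == sp
    if (any(in_sp)) {
      w[in_sp] <- w[in_sp] / sum(w[in_sp]) * cfg$species_mix[[sp]]
    }
  }
  uni$base_weight <- w
  # miRNA temporal archetypes (clusters peaking at different time points),
  # mirroring the observed cluster-size ordering (cluster 6 largest ... 1
  # smallest)
  uni$peak <- NA_integer_
  mi <- which(uni$class == "miRNA")
  if (length(mi) > 0) {
    peaks <- cfg$mirna_cluster_peaks
    probs <- c(0.05, 0.16, 0.14, 0.12, 0.21, 0.32)[seq_along(peaks)]
    uni$peak[mi] <- sample(peaks, length(mi), replace = TRUE,
                           prob = probs / sum(probs))
  }
  uni
}

#' Simulate collapsed small-RNA libraries
#'
#' Draws, for every time point and replicate, a collapsed-read library
#' (sequence, count) by multinomial sampling of a fixed fragment universe
#' built from the references. Expected class-level RPM follows
#' `cfg$class_dynamics`; miRNAs additionally carry per-cluster temporal
#' archetypes; bacterial fragments follow `cfg$exo_spike`. Total counts per
#' library equal `cfg$depth` exactly.
#'
#' @param refs references from [generate_toy_references()].
#' @param cfg a [sim_config()].
#' @return list of libraries, each a list with `sample_id`, `timepoint`,
#'   `replicate` and `reads` (data.frame `sequence`, `count`); the fragment
#'   universe with truth labels is attached as `attr(, "universe")`.
#' @export
generate_srna_libraries <- function(refs, cfg = sim_config()) {
  stopifnot(inherits(refs, "pmi_refs"))
  tps <- cfg$timepoints_h
  dyn <- cfg$class_dynamics
  if (ncol(dyn) != length(tps)) {
    stop("class_dynamics must have one column per time point", call. = FALSE)
  }
  if (any(dyn < 0)) stop("negative multipliers", call. = FALSE)
  needed <- rownames(dyn)[rownames(dyn) %in% c("tsRNA", "rsRNA", "miRNA")]
  with_seed(derive_seed(cfg$seed, "libraries"), {
    uni <- build_fragment_universe(refs, cfg)
    libs <- list()
    for (ti in seq_along(tps)) {
      for (r in seq_len(cfg$replicates)) {
        w <- uni$base_weight
        endo <- uni$class != "bacterial"
        mult <- rep(1, nrow(uni))
        mult[endo] <- dyn[uni$class[endo], ti]
        # miRNA archetypes: smooth bump peaking at the archetype time
        # point, rescaled to weighted mean one so the class total is
        # untouched by the within-class cluster structure
        mi <- !is.na(uni$peak)
        bump <- 0.6 + 1.8 * exp(-((ti - uni$peak[mi])^2) / 2.5)
        bump <- bump * sum(w[mi]) / sum(w[mi] * bump)
        mult[mi] <- mult[mi] * bump
        # RPM is compositional: the trajectory multipliers are planted as
        # relative-abundance (RPM-space) ratios, with the dominant flat
        # classes (rRNA-derived fragments and genomic background)
        # absorbing the complementary mass so the mapped total is
        # conserved in expectation
        buffer <- endo & uni$class %in% c("rsRNA", "other_ncRNA")
        nonbuf <- endo & !buffer
        mult[buffer] <- mult[buffer] * pmax(
          (sum(w[endo]) - sum(w[nonbuf] * mult[nonbuf])) /
            sum(w[buffer] * mult[buffer]), 0.05)
        # bacterial: global fraction trajectory plus the 30 h spike subset
        bact <- !endo
        if (any(bact)) {
          f <- cfg$exo_spike$frac[ti]
          mult[bact] <- f / sum(uni$base_weight[bact])
          if (ti == length(tps)) {
            mult[bact & uni$spike] <- mult[bact & uni$spike] *
              cfg$exo_spike$spike_mult
          }
        }
        ew <- w * mult
        if (cfg$noise_cv > 0) {
          sdlog <- sqrt(log(1 + cfg$noise_cv^2))
          ew <- ew * rlnorm(length(ew), -sdlog^2 / 2, sdlog)
        }
        counts <- rmultinom(1, cfg$depth, ew / sum(ew))[, 1]
        keep <- counts > 0
        libs[[length(libs) + 1]] <- list(
          sample_id = sprintf("T%02d_R%d", tps[ti], r),
          timepoint = tps[ti], replicate = r,
          reads = data.frame(sequence = uni$sequence[keep],
                             count = as.integer(counts[keep]),
                             stringsAsFactors = FALSE))
      }
    }
    names(libs) <- vapply(libs, `[[`, character(1), "sample_id")
    attr(libs, "universe") <- uni
    libs
  })
}

#' Simulate a RIN table
#'
#' `RIN(organ, t) = intercept - slope * t + noise`, clipped to `[1, 10]`,
#' for 8 organs, the configured time grid and replicate count. Each
#' (time point, replicate) pair is one animal measured across all organs.
#'
#' @param cfg a [sim_config()].
#' @return data.frame `organ`, `timepoint_h`, `replicate`, `animal_id`,
#'   `rin`.
#' @export
generate_rin_table <- function(cfg = sim_config()) {
  pars <- cfg$rin_params
  with_seed(derive_seed(cfg$seed, "rin"), {
    grid <- expand.grid(replicate = seq_len(cfg$rin_replicates),
                        timepoint_h = cfg$rin_timepoints_h,
                        organ = pars$organ, stringsAsFactors = FALSE)
    i <- match(grid$organ, pars$organ)
    rin <- pars$intercept[i] - pars$slope[i] * grid$timepoint_h +
      rnorm(nrow(grid), 0, pars$sd[i])
    grid$animal_id <- sprintf("M%02d_T%02d", grid$replicate, grid$timepoint_h)
    grid$rin <- pmin(10, pmax(1, rin))
    grid[, c("organ", "timepoint_h", "replicate", "animal_id", "rin")]
  })
}

#' Reshape a RIN table to an animals x organs feature matrix
#'
#' @param rin_table output of [generate_rin_table()] (or same columns).
#' @return list with `x` (animals x organs matrix) and `pmi_h` (hours).
#' @export
rin_feature_matrix <- function(rin_table) {
  wide <- stats::reshape(
    rin_table[, c("animal_id", "organ", "rin", "timepoint_h")],
    idvar = c("animal_id", "timepoint_h"), timevar = "organ",
    direction = "wide")
  x <- as.matrix(wide[, grep("^rin\\.", names(wide))])
  colnames(x) <- sub("^rin\\.", "", colnames(x))
  rownames(x) <- wide$animal_id
  list(x = x, pmi_h = wide$timepoint_h)
}

#' Simulate a delta-Ct qPCR matrix
#'
#' Animals receive uniform random PMIs on `[0, pmi_max_min]`; each
#' feature's delta-Ct is linear in PMI plus Gaussian cycle noise. Planted
#' biomarkers have positive slope under the default convention (expression
#' `2^(-dCt)` declines with PMI); the remaining features have slope zero.
#'
#' @param cfg a [sim_config()].
#' @return list with `x` (animals x features delta-Ct matrix), `pmi_min`,
#'   `biomarkers` (planted feature ids) and `params`.
#' @export
generate_deltact_matrix <- function(cfg = sim_config()) {
  pars <- cfg$deltact_params
  bio <- pars$feature[pars$slope > 0]
  if (nrow(pars) < length(bio)) stop("fewer features than planted biomarkers",
                                     call. = FALSE)
  if (cfg$n_animals < 2) stop("need at least two animals", call. = FALSE)
  sgn <- if (cfg$expression_sign == "negative") 1 else -1
  with_seed(derive_seed(cfg$seed, "deltact"), {
    pmi <- runif(cfg$n_animals, 0, cfg$pmi_max_min)
    x <- sapply(seq_len(nrow(pars)), function(j) {
      pars$intercept[j] + sgn * pars$slope[j] * pmi +
        rnorm(cfg$n_animals, 0, pars$sd[j])
    })
    colnames(x) <- pars$feature
    rownames(x) <- sprintf("A%03d", seq_len(cfg$n_animals))
    list(x = x, pmi_min = pmi, biomarkers = bio, params = pars)
  })
}

#' Simulate a miRNA-target context score table
#'
#' Emulates the format of a precomputed target-site efficacy table: one row
#' per (miRNA, gene) pair with a context score (<= 0; more negative =
#' stronger predicted repression) and a within-gene percentile. The output
#' always contains rows on both sides of the conventional score -0.2 /
#' percentile 90 filtering thresholds.
#'
#' @param refs references (for miRNA ids).
#' @param cfg a [sim_config()].
#' @param n_genes number of host gene ids.
#' @return data.frame `mirna`, `gene`, `context_score`, `percentile`.
#' @export
generate_context_table <- function(refs, cfg = sim_config(), n_genes = 120) {
  stopifnot(length(refs$mirnas) >= 1, n_genes >= 1)
  with_seed(derive_seed(cfg$seed, "context"), {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    rows <- lapply(names(refs$mirnas), function(mi) {
      gs <- sample(genes, min(n_genes, sample(8:20, 1)))
      data.frame(mirna = mi, gene = gs,
                 context_score = -round(runif(length(gs), 0, 0.6), 3),
                 percentile = round(runif(length(gs), 0, 100), 1),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    # fixture guarantee: at least one row on each side of the thresholds
    anchor <- data.frame(
      mirna = rep(names(refs$mirnas)[1], 3),
      gene = genes[1:3],
      context_score = c(-0.35, -0.05, -0.35),
      percentile = c(95, 95, 50), stringsAsFactors = FALSE)
    out <- rbind(anchor, out)
    rownames(out) <- NULL
    out
  })
}
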