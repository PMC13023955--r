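# End-to-end orchestration: one configuration object, deterministic
# per-stage seeds, validated file inputs and a run directory of TSV/JSON
# artifacts that is byte-identical across reruns of the same config.

#' Pipeline run configuration
#'
#' @param seed global seed; all stage seeds derive from it via
#'   [derive_seed()].
#' @param out_dir run directory (created by [run_all()]).
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "annotate", "dynamics", "rin", "selection",
#'   "final_model", "benchmark", "exogenous", "crosskingdom")`.
#' @param sim list of overrides passed to [sim_config()].
#' @param ref_sizes list of overrides for [generate_toy_references()].
#' @param stage1 list: `seeds`, `threshold`, `max_features`.
#' @param stage2 list: `seeds`, `top_k`, `min_inner_folds`, `core_size`.
#' @param rin list: `k`, `shap`.
#' @param clustering list: `c`, `m`, `tol`, `max_iter`.
#' @param final list: `k`, `shap`.
#' @param benchmark list: `k`.
#' @param exogenous list: `min_total`, `fc_threshold`, `q_threshold`.
#' @param targets list: `min_avg`, `score_max`, `pct_min`, `n_gene_sets`.
#' @return list of class `pmi_run_config`.
#' @export
run_config <- function(seed = 1, out_dir = "pmiclock_run",
                       stages = c("simulate", "annotate", "dynamics", "rin",
                                  "selection", "final_model", "exogenous",
                                  "crosskingdom"),
                       sim = list(), ref_sizes = list(),
                       stage1 = list(), stage2 = list(), rin = list(),
                       clustering = list(), final = list(),
                       benchmark = list(), exogenous = list(),
                       targets = list()) {
  dflt <- function(user, defaults) utils::modifyList(defaults, user)
  structure(list(
    seed = as.integer(seed), out_dir = out_dir, stages = stages,
    sim = sim, ref_sizes = ref_sizes,
    stage1 = dflt(stage1, list(seeds = 1:40, threshold = 35,
                               max_features = 24)),
    stage2 = dflt(stage2, list(seeds = 10:21, top_k = 3,
                               min_inner_folds = 2, core_size = NULL)),
    rin = dflt(rin, list(k = 10, shap = FALSE)),
    clustering = dflt(clustering, list(c = 6, m = 2, tol = 1e-6,
                                       max_iter = 200)),
    final = dflt(final, list(k = 15, shap = TRUE)),
    benchmark = dflt(benchmark, list(k = 15)),
    exogenous = dflt(exogenous, list(min_total = 1000, fc_threshold = 2,
                                     q_threshold = 0.01)),
    targets = dflt(targets, list(min_avg = 5, score_max = -0.2,
                                 pct_min = 90, n_gene_sets = 8))),
    class = "pmi_run_config")
}

# deterministic toy gene sets over a gene universe (cross-kingdom stage)
toy_gene_sets <- function(genes, n_sets = 8, seed = 1) {
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      sort(sample(genes, max(3, rbinom(1, length(genes), 0.12))))
    })
    names(sets) <- sprintf("set%02d", seq_len(n_sets))
    sets
  })
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the configured stages in order (simulate, annotate, dynamics,
#' RIN models, two-stage selection, final model, exogenous, cross-kingdom)
#' and writes every artifact under `config$out_dir`. Reruns with an
#' identical configuration produce byte-identical TSV/CSV/JSON artifacts;
#' each run directory carries the seed and a config checksum.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return invisibly a list with the in-memory stage results.
#' @export
run_all <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pmi_run_config"))
  say <- function(...) if (!quiet) message("[pmiclock] ", sprintf(...))
  t_start <- Sys.time()
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  stage_on <- function(s) s %in% config$stages

  # config echo + checksum (written first; the checksum covers the yaml)
  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(config[setdiff(names(config), "out_dir")], cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  writeLines(c(sprintf("seed: %d", config$seed),
               sprintf("config_md5: %s", cfg_hash)),
             file.path(out, "RUN_INFO.txt"))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # ---- simulate ------------------------------------------------------
  if (stage_on("simulate")) {
    run_stage("simulate", {
      say("simulate: toy references + libraries + RIN + delta-Ct")
      cfg <- do.call(sim_config, utils::modifyList(
        list(seed = derive_seed(config$seed, "sim")), config$sim))
      refs <- do.call(generate_toy_references,
                      list(seed = derive_seed(config$seed, "refs"),
                           sizes = config$ref_sizes))
      validate_reference_set(refs)
      libs <- generate_srna_libraries(refs, cfg)
      rin_tab <- generate_rin_table(cfg)
      dct <- generate_deltact_matrix(cfg)
      ctx <- generate_context_table(refs, cfg)
      write_reference_fasta(refs, file.path(out, "references"))
      write_library_tsv(libs, file.path(out, "libraries"))
      write_rin_csv(rin_tab, file.path(out, "rin.csv"))
      write_deltact_csv(dct, file.path(out, "deltact.csv"))
      write_table_meta(ctx, file.path(out, "context_scores.tsv"))
      res$sim <- list(cfg = cfg, refs = refs, libs = libs,
                       rin = rin_tab, dct = dct, ctx = ctx)
    })
  }

  # ---- annotate ------------------------------------------------------
  if (stage_on("annotate")) {
    run_stage("annotate", {
      say("annotate: %d libraries", length(res$sim$libs))
      dir.create(file.path(out, "annotation"), showWarnings = FALSE)
      anns <- lapply(res$sim$libs, annotate_library, refs = res$sim$refs)
      for (nm in names(anns)) {
        write_table_meta(anns[[nm]],
                         file.path(out, "annotation", paste0(nm, ".tsv")))
      }
      cm <- build_count_matrix(anns, by = "parent")
      cm_class <- build_count_matrix(anns, by = "class")
      wr_mat <- function(m, path) {
        df <- data.frame(feature = rownames(m), as.data.frame(m),
                         check.names = FALSE)
        write_table_meta(df, path)
      }
      wr_mat(cm$counts, file.path(out, "annotation", "counts.tsv"))
      wr_mat(round(cm$rpm, 4), file.path(out, "annotation", "rpm.tsv"))
      wr_mat(cm_class$counts, file.path(out, "annotation", "class_counts.tsv"))
      res$annotation <- list(anns = anns, cm = cm, cm_class = cm_class)
    })
  }

  # ---- dynamics ------------------------------------------------------
  if (stage_on("dynamics")) {
    run_stage("dynamics", {
      say("dynamics: class time-course tests + miRNA clustering")
      dir.create(file.path(out, "dynamics"), showWarnings = FALSE)
      libs <- res$sim$libs
      tp <- setNames(vapply(libs, `[[`, numeric(1), "timepoint"),
                     names(libs))
      crt <- class_rpm_table(res$annotation$cm_class, tp)
      tests <- class_timecourse_test(crt)
      write_table_meta(tests, file.path(out, "dynamics", "class_tests.tsv"))

      rpm <- res$annotation$cm$rpm
      mir <- rownames(rpm)[res$annotation$cm$feature_class[rownames(rpm)] ==
                             "miRNA"]
      z <- standardize_profiles(rpm[mir, , drop = FALSE], tp)
      cl <- config$clustering
      fcm <- fcm_cluster(z, c = cl$c, m = cl$m, tol = cl$tol,
                         max_iter = cl$max_iter,
                         seed = derive_seed(config$seed, "fcm"))
      memb <- data.frame(feature = rownames(fcm$membership),
                         fcm$membership, check.names = FALSE)
      write_table_meta(memb, file.path(out, "dynamics", "membership.tsv"))
      hard <- apply(fcm$membership, 1, which.max)
      write_table_meta(
        data.frame(feature = rownames(fcm$membership),
                   cluster = colnames(fcm$membership)[hard]),
        file.path(out, "dynamics", "cluster_assignments.tsv"))
      write_table_meta(cluster_summary(fcm),
                       file.path(out, "dynamics", "cluster_summary.tsv"))
      res$dynamics <- list(tests = tests, fcm = fcm, z = z,
                            clusters = setNames(colnames(fcm$membership)[hard],
                                                rownames(fcm$membership)))
    })
  }

  # ---- rin -----------------------------------------------------------
  if (stage_on("rin")) {
    run_stage("rin", {
      say("rin: per-organ fits + four-model benchmark")
      dir.create(file.path(out, "rin_models"), showWarnings = FALSE)
      lin <- fit_linear_per_organ(res$sim$rin)
      write_table_meta(lin, file.path(out, "rin_models", "per_organ.tsv"))
      fm <- rin_feature_matrix(res$sim$rin)
      reports <- fit_rin_pmi_models(fm$x, fm$pmi_h, k = config$rin$k,
                                    seed = config$seed,
                                    shap = config$rin$shap)
      metrics <- lapply(reports, function(r) as.list(round(r$metrics, 6)))
      write_json_artifact(metrics, file.path(out, "rin_models",
                                             "metrics.json"))
      imp <- do.call(rbind, lapply(names(reports), function(nm) {
        data.frame(model = nm, organ = names(reports[[nm]]$importance),
                   importance = as.numeric(reports[[nm]]$importance))
      }))
      write_table_meta(imp, file.path(out, "rin_models", "importance.tsv"))
      for (nm in names(reports)) {
        write_table_meta(reports[[nm]]$predictions,
                         file.path(out, "rin_models",
                                   paste0("oof_", nm, ".csv")))
      }
      res$rin_models <- list(linear = lin, reports = reports,
                              features = fm)
    })
  }

  # ---- selection -----------------------------------------------------
  if (stage_on("selection")) {
    run_stage("selection", {
      say("selection: stage-1 RFE stability screen")
      dir.create(file.path(out, "selection"), showWarnings = FALSE)
      rpm <- res$annotation$cm$rpm
      fcls <- res$annotation$cm$feature_class[rownames(rpm)]
      cand_rows <- rownames(rpm)[fcls %in% c("tsRNA", "mt-tsRNA", "piRNA")]
      keep <- head(cand_rows[order(-rowMeans(rpm[cand_rows, , drop = FALSE]))],
                   config$stage1$max_features)
      x1 <- t(rpm[keep, , drop = FALSE])
      tp <- vapply(res$sim$libs, `[[`, numeric(1), "timepoint")
      s1 <- stage1_candidate_selection(
        x1, tp, seeds = config$stage1$seeds,
        threshold = config$stage1$threshold)
      write_json_artifact(
        list(candidates = s1$candidates,
             frequency = as.list(setNames(as.integer(s1$frequency),
                                          names(s1$frequency))),
             threshold = s1$threshold, n_seeds = s1$n_seeds),
        file.path(out, "selection", "stage1.json"))

      say("selection: stage-2 nested RFECV over %d seeds",
          length(config$stage2$seeds))
      dct <- res$sim$dct
      s2 <- stage2_core_biomarkers(
        dct$x, dct$pmi_min, seeds = config$stage2$seeds,
        top_k = config$stage2$top_k,
        min_inner_folds = config$stage2$min_inner_folds,
        core_size = config$stage2$core_size)
      write_json_artifact(
        list(core = s2$core, low_confidence = s2$low_confidence,
             recurrence = as.list(setNames(as.integer(s2$recurrence),
                                           names(s2$recurrence))),
             retained_seeds = s2$retained_seeds,
             seed_scores = as.list(round(s2$seed_scores, 6))),
        file.path(out, "selection", "stage2.json"))
      res$selection <- list(stage1 = s1, stage2 = s2)
    })
  }

  # ---- benchmark (optional) -----------------------------------------
  if (stage_on("benchmark")) {
    run_stage("benchmark", {
      say("benchmark: nine models on the qPCR panel")
      dct <- res$sim$dct
      bm <- benchmark_nine_models(dct$x, dct$pmi_min,
                                  k = config$benchmark$k,
                                  seed = config$seed)
      write_json_artifact(
        lapply(bm, function(r) as.list(round(r$metrics, 6))),
        file.path(out, "benchmark_metrics.json"))
      res$benchmark <- bm
    })
  }

  # ---- final model ---------------------------------------------------
  if (stage_on("final_model")) {
    run_stage("final_model", {
      dct <- res$sim$dct
      core <- res$selection$stage2$core
      if (length(core) == 0) core <- res$sim$dct$biomarkers
      say("final_model: RF on %d core biomarkers", length(core))
      fin <- final_model(dct$x, dct$pmi_min, core, k = config$final$k,
                         seed = config$seed, shap = config$final$shap)
      dir.create(file.path(out, "final_model"), showWarnings = FALSE)
      write_json_artifact(
        list(core_features = core,
             metrics = as.list(round(fin$metrics, 6))),
        file.path(out, "final_model", "metrics.json"))
      write_table_meta(fin$predictions,
                       file.path(out, "final_model", "oof_predictions.csv"))
      write_table_meta(
        data.frame(feature = names(fin$importance),
                   importance = as.numeric(fin$importance)),
        file.path(out, "final_model", "importance.tsv"))
      if (!is.null(fin$shap)) {
        write_table_meta(fin$shap, file.path(out, "final_model", "shap.tsv"))
      }
      res$final <- fin
    })
  }

  # ---- exogenous -----------------------------------------------------
  if (stage_on("exogenous")) {
    run_stage("exogenous", {
      say("exogenous: host-unmapped fragments + NB Wald test")
      dir.create(file.path(out, "exogenous"), showWarnings = FALSE)
      libs <- res$sim$libs
      refs <- res$sim$refs
      exo <- extract_unmapped(libs, refs$host_genome)
      flt <- filter_low_abundance(exo, config$exogenous$min_total)
      write_table_meta(flt, file.path(out, "exogenous", "fragments.tsv"))
      tp <- vapply(libs, `[[`, numeric(1), "timepoint")
      ends <- range(tp)
      use <- names(libs)[tp %in% ends]
      de <- NULL
      if (nrow(flt) >= 1) {
        cnt <- as.matrix(flt[, use, drop = FALSE])
        rownames(cnt) <- flt$fragment
        de <- nb_wald_test(cnt, groups = factor(tp[use], levels = ends),
                           fc_threshold = config$exogenous$fc_threshold,
                           q_threshold = config$exogenous$q_threshold)
        write_table_meta(de, file.path(out, "exogenous", "de_results.tsv"))
      }
      tax <- assign_taxonomy(flt$fragment, refs$bacterial_genomes)
      comp <- species_composition(flt, tax)
      write_table_meta(comp, file.path(out, "exogenous", "composition.csv"))
      traj <- species_match_trajectory(
        libs, refs$bacterial_genomes["Staphylococcus_aureus"])
      write_table_meta(traj, file.path(out, "exogenous", "trajectory.csv"))
      res$exogenous <- list(fragments = flt, de = de, taxonomy = tax,
                             composition = comp, trajectory = traj)
    })
  }

  # ---- cross-kingdom -------------------------------------------------
  if (stage_on("crosskingdom")) {
    run_stage("crosskingdom", {
      say("crosskingdom: target filtering + enrichment + seed scan")
      dir.create(file.path(out, "crosskingdom"), showWarnings = FALSE)
      refs <- res$sim$refs
      cm <- res$annotation$cm
      mir_rows <- rownames(cm$counts)[cm$feature_class[rownames(cm$counts)] ==
                                        "miRNA"]
      expressed <- filter_expressed_mirnas(
        cm$counts[mir_rows, , drop = FALSE], config$targets$min_avg)
      ctx <- res$sim$ctx
      flt <- filter_targets(ctx[ctx$mirna %in% expressed, ],
                            config$targets$score_max, config$targets$pct_min)
      write_table_meta(flt, file.path(out, "crosskingdom",
                                      "filtered_targets.tsv"))
      universe <- sort(unique(ctx$gene))
      sets <- toy_gene_sets(universe, config$targets$n_gene_sets,
                            seed = derive_seed(config$seed, "gene_sets"))
      enr <- hypergeometric_enrichment(unique(flt$gene), sets, universe)
      write_table_meta(enr, file.path(out, "crosskingdom", "enrichment.tsv"))

      mir_seq <- refs$mirnas[intersect(names(refs$mirnas), expressed)]
      hits <- seed_scan_targets(mir_seq, refs$bacterial_cds)
      write_table_meta(hits, file.path(out, "crosskingdom", "seed_hits.tsv"))
      cl <- res$dynamics$clusters
      hits_cl <- hits[hits$mirna %in% names(cl), , drop = FALSE]
      if (nrow(hits_cl) > 0) {
        summ <- cluster_target_summary(hits_cl, cl)
        write_table_meta(summ$per_mirna,
                         file.path(out, "crosskingdom", "cluster_targets.tsv"))
        write_table_meta(
          data.frame(cluster = rownames(summ$category_pct),
                     as.data.frame.matrix(round(summ$category_pct, 4)),
                     check.names = FALSE),
          file.path(out, "crosskingdom", "category_pct.tsv"))
        res$crosskingdom <- list(filtered = flt, enrichment = enr,
                                  hits = hits, summary = summ)
      } else {
        res$crosskingdom <- list(filtered = flt, enrichment = enr,
                                  hits = hits, summary = NULL)
      }
    })
  }

  say("done in %.1f s; artifacts in %s",
      as.numeric(difftime(Sys.time(), t_start, units = "secs")), out)
  invisible(res)
}

#' Validate pipeline input files
#'
#' Schema checks with row-level messages: RIN CSV (columns, RIN within
#' [1, 10], time points >= 0), delta-Ct CSV (finite values, PMI >= 0),
#' collapsed-library directory (ACGT alphabet, positive integer counts,
#' unique sequences per library).
#'
#' @param rin_csv,deltact_csv,library_dir paths (any may be `NULL` to
#'   skip).
#' @return data.frame report (one row per checked file) when everything
#'   passes; otherwise an error naming the file and rows.
#' @export
validate_inputs <- function(rin_csv = NULL, deltact_csv = NULL,
                            library_dir = NULL) {
  problems <- character(0)
  report <- list()
  if (!is.null(rin_csv)) {
    d <- read.csv(rin_csv, stringsAsFactors = FALSE)
    need <- c("organ", "timepoint_h", "replicate", "rin")
    miss <- setdiff(need, names(d))
    if (length(miss)) {
      problems <- c(problems, sprintf("%s: missing columns %s", rin_csv,
                                      paste(miss, collapse = ", ")))
    } else {
      bad <- which(!is.finite(d$rin) | d$rin < 1 | d$rin > 10)
      if (length(bad)) {
        problems <- c(problems,
                      sprintf("%s: RIN outside [1, 10] at rows %s", rin_csv,
                              paste(head(bad, 5), collapse = ", ")))
      }
      bad_t <- which(d$timepoint_h < 0)
      if (length(bad_t)) {
        problems <- c(problems, sprintf("%s: negative time at rows %s",
                                        rin_csv,
                                        paste(head(bad_t, 5), collapse = ", ")))
      }
      report$rin <- data.frame(file = rin_csv, rows = nrow(d), status = "ok")
    }
  }
  if (!is.null(deltact_csv)) {
    d <- read.csv(deltact_csv, stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(c("animal_id", "pmi_min") %in% names(d))) {
      problems <- c(problems, sprintf("%s: missing animal_id/pmi_min columns",
                                      deltact_csv))
    } else {
      bad <- which(d$pmi_min < 0)
      if (length(bad)) {
        problems <- c(problems, sprintf("%s: negative PMI at rows %s",
                                        deltact_csv,
                                        paste(head(bad, 5), collapse = ", ")))
      }
      vals <- as.matrix(d[, setdiff(names(d), c("animal_id", "pmi_min"))])
      if (any(!is.finite(vals))) {
        problems <- c(problems, sprintf("%s: non-finite delta-Ct values",
                                        deltact_csv))
      }
      report$deltact <- data.frame(file = deltact_csv, rows = nrow(d),
                                   status = "ok")
    }
  }
  if (!is.null(library_dir)) {
    libs <- read_library_tsv(library_dir)
    for (lib in libs) {
      f <- file.path(library_dir, paste0(lib$sample_id, ".tsv"))
      bad <- which(grepl("[^ACGT]", lib$reads$sequence))
      if (length(bad)) {
        problems <- c(problems, sprintf("%s: non-ACGT sequence at rows %s", f,
                                        paste(head(bad, 5), collapse = ", ")))
      }
      badc <- which(lib$reads$count < 1 | lib$reads$count != round(lib$reads$count))
      if (length(badc)) {
        problems <- c(problems, sprintf("%s: invalid counts at rows %s", f,
                                        paste(head(badc, 5), collapse = ", ")))
      }
      if (anyDuplicated(lib$reads$sequence)) {
        problems <- c(problems, sprintf("%s: duplicate sequences", f))
      }
    }
    report$libraries <- data.frame(file = library_dir, rows = length(libs),
                                   status = "ok")
  }
  if (length(problems)) {
    stop(paste(problems, collapse = "\n"), call. = FALSE)
  }
  do.call(rbind, report)
}
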