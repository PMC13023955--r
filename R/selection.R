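# Two-stage multi-seed stability selection of PMI biomarkers and the
# cross-validated model benchmarks around it.
#
# Stage 1 (sequencing screen): per seed, random-forest recursive feature
# elimination scored by repeated k-fold CV; the per-seed optimal subset is
# the RFE step with the best mean R^2. Features recurring in more than a
# threshold number of per-seed subsets become candidates.
#
# Stage 2 (qPCR panel): per seed, 5-fold outer CV with RFECV (inner 5-fold
# CV, R^2 metric) inside each training fold; seeds are ranked by mean
# outer R^2, the best seeds retained, features selected in enough inner
# folds collected, and the core set cut at the largest recurrence gap.

#' Remove zero-variance features
#'
#' @param x samples x features matrix.
#' @return list `kept` (matrix), `removed` (feature names).
#' @export
filter_zero_sd <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, sd)
  removed <- colnames(x)[sds == 0]
  kept <- x[, sds > 0, drop = FALSE]
  if (ncol(kept) == 0) stop("all features have zero standard deviation",
                            call. = FALSE)
  list(kept = kept, removed = removed)
}

# One RFE path: starting from all features, repeatedly fit the forest,
# record the fit (optionally scoring a held-out set at each size), and
# drop the least important feature. Returns elimination order and, when
# a test set is given, the per-size test R^2.
rf_rfe_path <- function(x_train, y_train, x_test = NULL, y_test = NULL,
                        num_trees = 500, min_split = 3, min_leaf = 1,
                        seed = 1) {
  feats <- colnames(x_train)
  p <- length(feats)
  active <- feats
  sizes <- integer(0); scores <- numeric(0)
  order_removed <- character(0)
  step <- 0
  while (TRUE) {
    step <- step + 1
    fit <- rf_regress(x_train[, active, drop = FALSE], y_train,
                      num_trees = num_trees, mtry = "sqrt",
                      min_split = min_split, min_leaf = min_leaf,
                      seed = seed + step)
    if (!is.null(x_test)) {
      pred <- predict(fit, x_test[, active, drop = FALSE])
      sizes <- c(sizes, length(active))
      sst <- sum((y_test - mean(y_test))^2)
      scores <- c(scores,
                  if (sst == 0) NA_real_ else 1 - sum((y_test - pred)^2) / sst)
    } else {
      sizes <- c(sizes, length(active))
    }
    if (length(active) == 1) break
    worst <- active[which.min(fit$importance[active])]
    order_removed <- c(order_removed, worst)
    active <- setdiff(active, worst)
  }
  # elimination order, last survivor first in rank (rank 1 = kept longest)
  ranking <- c(active, rev(order_removed))
  list(sizes = sizes, scores = scores, ranking = ranking)
}

# Features surviving an RFE run down to `size` (the `size` best-ranked).
rfe_subset <- function(ranking, size) ranking[seq_len(size)]

#' Stage-1 candidate selection by multi-seed RFE stability
#'
#' For each seed, random-forest RFE is scored by repeated k-fold CV
#' (default three repeats of five folds): every fold contributes a test
#' R^2 per subset size along its own elimination path, the size with the
#' best mean R^2 wins (ties go to the smaller subset), and the seed's
#' optimal subset is the RFE ranking on the full data cut at that size.
#' Candidates are the features present in strictly more than `threshold`
#' of the per-seed subsets.
#'
#' @param x samples x features matrix (e.g. RPM).
#' @param y PMI per sample.
#' @param seeds integer vector of selection seeds (default `1:40`).
#' @param threshold candidate rule: present in `> threshold` subsets.
#' @param n_repeats,k repeated k-fold CV design.
#' @param num_trees forest size used throughout.
#' @return list of class `pmi_stage1`: `candidates`, `frequency`,
#'   `subsets` (per seed), `threshold`, `n_seeds`.
#' @export
stage1_candidate_selection <- function(x, y, seeds = 1:40, threshold = 35,
                                       n_repeats = 3, k = 5,
                                       num_trees = 500) {
  x <- as.matrix(x)
  if (threshold >= length(seeds)) {
    stop("threshold must be smaller than the number of seeds", call. = FALSE)
  }
  if (nrow(x) < 10) stop("need at least 10 samples", call. = FALSE)
  x <- filter_zero_sd(x)$kept
  subsets <- lapply(seeds, function(s) {
    score_by_size <- matrix(NA_real_, ncol(x), n_repeats * k)
    col <- 0
    for (r in seq_len(n_repeats)) {
      folds <- cv_folds(nrow(x), k, seed = derive_seed(s, paste0("rep", r)))
      for (f in seq_along(folds)) {
        col <- col + 1
        test <- folds[[f]]
        path <- rf_rfe_path(x[-test, , drop = FALSE], y[-test],
                            x[test, , drop = FALSE], y[test],
                            num_trees = num_trees,
                            seed = derive_seed(s, sprintf("r%df%d", r, f)))
        score_by_size[path$sizes, col] <- path$scores
      }
    }
    mean_r2 <- rowMeans(score_by_size, na.rm = TRUE)
    best_size <- which(mean_r2 == max(mean_r2, na.rm = TRUE))[1]  # ties: smaller
    full <- rf_rfe_path(x, y, num_trees = num_trees,
                        seed = derive_seed(s, "full"))
    sort(rfe_subset(full$ranking, best_size))
  })
  names(subsets) <- paste0("seed", seeds)
  stage1_candidates(subsets, threshold)
}

#' Apply the stage-1 recurrence threshold to per-seed subsets
#'
#' Exposed separately so the strict `> threshold` rule can be exercised on
#' constructed subset lists.
#'
#' @param subsets list of character vectors (one optimal subset per seed).
#' @param threshold candidate rule: present in `> threshold` subsets.
#' @return list of class `pmi_stage1`.
#' @export
stage1_candidates <- function(subsets, threshold = 35) {
  freq <- table(unlist(lapply(subsets, unique)))
  freq <- sort(freq, decreasing = TRUE)
  structure(list(
    candidates = sort(names(freq)[freq > threshold]),
    frequency = freq, subsets = subsets,
    threshold = threshold, n_seeds = length(subsets)),
    class = "pmi_stage1")
}

# RFECV on one training fold: inner k-fold CV, each inner fold scoring its
# own RFE path at every size; the size with the best mean inner R^2 (ties:
# smaller) is selected and the final subset comes from an RFE ranking on
# the whole training fold.
rfecv_select <- function(x, y, inner_k = 5, num_trees = 500, min_split = 3,
                         min_leaf = 1, seed = 1) {
  folds <- cv_folds(nrow(x), inner_k, seed = seed)
  score_by_size <- matrix(NA_real_, ncol(x), length(folds))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    path <- rf_rfe_path(x[-test, , drop = FALSE], y[-test],
                        x[test, , drop = FALSE], y[test],
                        num_trees = num_trees, min_split = min_split,
                        min_leaf = min_leaf,
                        seed = derive_seed(seed, paste0("inner", f)))
    score_by_size[path$sizes, f] <- path$scores
  }
  mean_r2 <- rowMeans(score_by_size, na.rm = TRUE)
  best_size <- which(mean_r2 == max(mean_r2, na.rm = TRUE))[1]
  full <- rf_rfe_path(x, y, num_trees = num_trees, min_split = min_split,
                      min_leaf = min_leaf, seed = derive_seed(seed, "refit"))
  sort(rfe_subset(full$ranking, best_size))
}

#' Stage-2 core biomarkers by nested multi-seed RFECV
#'
#' Per seed: 5-fold outer cross-validation; within each outer training
#' fold, RFECV (inner 5-fold CV, R^2 metric) selects a feature subset, a
#' forest on the selected features predicts the outer test fold, and the
#' seed is scored by its mean outer R^2. The `top_k` best-scoring seeds
#' are retained; within each, features selected in at least
#' `min_inner_folds` of the five outer-fold selections are collected; the
#' core set consists of the features with the highest recurrence across
#' retained seeds, cut at the largest drop in recurrence count. When the
#' recurrence profile is flat (no gap), the seven most recurrent features
#' are returned flagged low-confidence.
#'
#' @param x samples x features matrix (delta-Ct).
#' @param y PMI per sample (minutes).
#' @param seeds seed grid (default the full `10:999`; scale down for desk
#'   runs).
#' @param top_k seeds retained by outer R^2 ranking.
#' @param min_inner_folds recurrence requirement within a seed.
#' @param outer_k outer folds.
#' @param core_size force a fixed core-set size instead of the gap cut.
#' @param num_trees,min_split,min_leaf forest hyperparameters (defaults:
#'   500 trees, sqrt feature subsampling, `min_split = 3`,
#'   `min_leaf = 1`).
#' @return list of class `pmi_stage2`: `core`, `low_confidence`,
#'   `recurrence`, `seed_scores`, `retained_seeds`, `per_seed_features`.
#' @export
stage2_core_biomarkers <- function(x, y, seeds = 10:999, top_k = 40,
                                   min_inner_folds = 2, outer_k = 5,
                                   core_size = NULL, num_trees = 500,
                                   min_split = 3, min_leaf = 1) {
  x <- as.matrix(x)
  if (length(seeds) < top_k) {
    stop("seed range smaller than top_k", call. = FALSE)
  }
  if (nrow(x) < 20) stop("need at least 20 samples", call. = FALSE)
  per_seed <- lapply(seeds, function(s) {
    folds <- cv_folds(nrow(x), outer_k, seed = s)
    sel_list <- vector("list", length(folds))
    r2 <- numeric(length(folds))
    for (f in seq_along(folds)) {
      test <- folds[[f]]
      xtr <- x[-test, , drop = FALSE]; ytr <- y[-test]
      sel <- rfecv_select(xtr, ytr, inner_k = 5, num_trees = num_trees,
                          min_split = min_split, min_leaf = min_leaf,
                          seed = derive_seed(s, paste0("outer", f)))
      sel_list[[f]] <- sel
      fit <- rf_regress(xtr[, sel, drop = FALSE], ytr,
                        num_trees = num_trees, mtry = "sqrt",
                        min_split = min_split, min_leaf = min_leaf,
                        seed = derive_seed(s, paste0("fit", f)))
      pred <- predict(fit, x[test, sel, drop = FALSE])
      r2[f] <- 1 - sum((y[test] - pred)^2) / sum((y[test] - mean(y[test]))^2)
    }
    sel_tab <- table(unlist(lapply(sel_list, unique)))
    list(score = mean(r2),
         features = sort(names(sel_tab)[sel_tab >= min_inner_folds]),
         selections = sel_list)
  })
  names(per_seed) <- paste0("seed", seeds)
  scores <- vapply(per_seed, `[[`, numeric(1), "score")
  retained <- order(scores, decreasing = TRUE)[seq_len(top_k)]
  rec <- table(unlist(lapply(per_seed[retained], `[[`, "features")))
  rec <- sort(rec, decreasing = TRUE)
  low_confidence <- FALSE
  if (length(rec) == 0) {
    core <- character(0)
    low_confidence <- TRUE
  } else if (!is.null(core_size)) {
    core <- names(rec)[seq_len(min(core_size, length(rec)))]
  } else {
    gaps <- -diff(as.numeric(rec))
    if (length(gaps) == 0 || max(gaps) == 0) {
      core <- names(rec)[seq_len(min(7, length(rec)))]
      low_confidence <- TRUE
    } else {
      cut_at <- which.max(gaps)  # first occurrence of the largest drop
      core <- names(rec)[seq_len(cut_at)]
    }
  }
  structure(list(
    core = sort(core), low_confidence = low_confidence, recurrence = rec,
    seed_scores = scores, retained_seeds = seeds[retained],
    per_seed_features = lapply(per_seed, `[[`, "features")),
    class = "pmi_stage2")
}

#' Nine-model benchmark on a qPCR panel
#'
#' Evaluates the nine regression algorithms of the panel benchmark --
#' random forest (500 trees, sqrt), distance-weighted 3-NN, gradient
#' boosting with linear and DART boosters, SVR with radial and linear
#' kernels, ridge and lasso with leave-one-out tuning, and the 50-20
#' network -- under seeded 15-fold cross-validation with pooled
#' out-of-fold metrics.
#'
#' @param x samples x features delta-Ct matrix.
#' @param y PMI (minutes).
#' @param k folds (default 15).
#' @param seed integer seed.
#' @return named list of `pmi_cv` objects.
#' @export
benchmark_nine_models <- function(x, y, k = 15, seed = 1) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds the number of samples", call. = FALSE)
  spec <- list(
    rf = list(family = "rf",
              params = list(num_trees = 500, mtry = "sqrt")),
    knn = list(family = "knn", params = list(k_neighbors = 3)),
    xgb_linear = list(family = "xgb_linear", params = list()),
    xgb_dart = list(family = "xgb_dart", params = list()),
    svr_radial = list(family = "svr_radial", params = list()),
    svr_linear = list(family = "svr_linear", params = list()),
    ridge = list(family = "ridge", params = list()),
    lasso = list(family = "lasso", params = list()),
    ann = list(family = "ann", params = list(hidden = c(50, 20))))
  out <- lapply(names(spec), function(nm) {
    cv_regress(x, y, family = spec[[nm]]$family, k = k,
               seed = derive_seed(seed, paste0("bench_", nm)),
               tune_folds = nrow(x),  # leave-one-out for ridge/lasso
               params = spec[[nm]]$params)
  })
  names(out) <- names(spec)
  out
}

#' Final random-forest PMI model on the core biomarkers
#'
#' Random forest (500 trees, sqrt feature subsampling, `min_split = 3`,
#' `min_leaf = 1`) on the core features, evaluated by seeded 15-fold CV
#' with pooled out-of-fold metrics; normalized importance and exact
#' interventional Shapley attributions (background = full matrix) are
#' attached.
#'
#' @param x samples x features delta-Ct matrix.
#' @param y PMI (minutes).
#' @param core_features feature subset for the final model.
#' @param k folds.
#' @param seed integer seed.
#' @param shap compute per-animal Shapley attributions.
#' @return a `pmi_cv` object with elements `importance` and (optionally)
#'   `shap`.
#' @export
final_model <- function(x, y, core_features, k = 15, seed = 1, shap = TRUE) {
  x <- as.matrix(x)
  if (length(core_features) == 0) stop("empty core feature set", call. = FALSE)
  if (!all(core_features %in% colnames(x))) {
    stop("core features missing from the matrix", call. = FALSE)
  }
  xs <- x[, core_features, drop = FALSE]
  cv <- cv_regress(xs, y, family = "rf", k = k,
                   seed = derive_seed(seed, "final"),
                   params = list(num_trees = 500, mtry = "sqrt",
                                 min_split = 3, min_leaf = 1))
  if (shap && length(core_features) <= 12) {
    fit <- cv$full_fit
    cv$shap <- shapley_table(function(nd) predict(fit, nd), xs, xs)
  }
  cv
}
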