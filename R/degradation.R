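# RNA-integrity (RIN) degradation models: per-organ linear RIN-vs-PMI
# regression and the four-model multi-organ PMI regression benchmark.

#' Per-organ linear regression of RIN on postmortem time
#'
#' Ordinary least squares of RIN on time, per organ, with the slope t-test
#' p-value -- the conventional first look at organ-specific degradation
#' clocks.
#'
#' @param rin_table data.frame with `organ`, `timepoint_h`, `rin`.
#' @return data.frame `organ`, `slope` (RIN/h), `intercept`, `r_squared`,
#'   `p_value`, `slope_se`, `n`.
#' @export
fit_linear_per_organ <- function(rin_table) {
  stopifnot(all(c("organ", "timepoint_h", "rin") %in% names(rin_table)))
  rows <- lapply(split(rin_table, rin_table$organ), function(d) {
    if (length(unique(d$timepoint_h)) < 3) {
      stop(sprintf("organ %s has fewer than 3 distinct time points",
                   d$organ[1]), call. = FALSE)
    }
    fit <- lm(rin ~ timepoint_h, data = d)
    sm <- summary(fit)
    data.frame(organ = d$organ[1],
               slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4],
               slope_se = sm$coefficients[2, 2],
               n = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multi-organ RIN-based PMI regression benchmark
#'
#' Evaluates the four regressor families used for RIN-based PMI
#' prediction -- lasso, elastic net (both tuned by inner 10-fold CV),
#' random forest with 100 trees, and a 50-20 ReLU network trained with
#' Adam -- by seeded k-fold cross-validation with pooled out-of-fold
#' metrics, and attaches normalized feature importance per model.
#'
#' @param x animals x organs RIN feature matrix.
#' @param pmi_h PMI per animal, hours.
#' @param models subset of `c("lasso", "enet", "rf", "ann")`.
#' @param k outer CV folds.
#' @param seed integer seed.
#' @param shap also compute exact interventional Shapley values for every
#'   animal (background = full feature matrix).
#' @return named list of `pmi_cv` objects, one per model, each with a
#'   `shap` element when requested.
#' @export
fit_rin_pmi_models <- function(x, pmi_h, models = c("lasso", "enet", "rf",
                                                    "ann"),
                               k = 10, seed = 1, shap = FALSE) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds the number of animals", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite RIN features", call. = FALSE)
  params <- list(
    lasso = list(),
    enet = list(),
    rf = list(num_trees = 100, mtry = "all", min_split = 2, min_leaf = 1),
    ann = list(hidden = c(50, 20), epochs = 2000, lr = 1e-3))
  out <- lapply(models, function(m) {
    cv <- cv_regress(x, pmi_h, family = if (m == "rf") "rf" else m,
                     k = k, seed = derive_seed(seed, paste0("rin_", m)),
                     tune_folds = 10, params = params[[m]])
    if (shap) {
      fit <- cv$full_fit
      cv$shap <- shapley_table(function(nd) predict(fit, nd), x, x)
    }
    cv
  })
  names(out) <- models
  out
}
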