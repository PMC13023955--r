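# Shared regression metrics, per-family normalized feature importance and
# exact interventional Shapley attribution for small feature panels.

#' Regression metrics
#'
#' `R^2 = 1 - SS_res / SS_tot` (can be negative for out-of-fold
#' predictions), mean absolute error and root mean squared error in target
#' units.
#'
#' @param y observed values.
#' @param y_hat predictions.
#' @return named numeric vector `r_squared`, `mae`, `rmse`.
#' @export
regression_metrics <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 2) {
    stop("y and y_hat must have equal length >= 2", call. = FALSE)
  }
  if (any(!is.finite(y)) || any(!is.finite(y_hat))) {
    stop("non-finite values", call. = FALSE)
  }
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("constant y: R^2 undefined", call. = FALSE)
  c(r_squared = 1 - sum((y - y_hat)^2) / ss_tot,
    mae = mean(abs(y - y_hat)),
    rmse = sqrt(mean((y - y_hat)^2)))
}

#' Normalized feature importance by model family
#'
#' Family-specific raw scores rescaled to sum to one: absolute
#' standardized coefficients for penalized linear models, impurity
#' importance for random forests, and the summed absolute input-to-first-
#' hidden-layer weights for the neural network.
#'
#' @param fit a fitted model from [fit_model()] or [rf_regress()].
#' @return named numeric vector summing to 1 (uniform when all raw scores
#'   are zero).
#' @export
normalized_importance <- function(fit) {
  raw <- if (inherits(fit, "pmi_rf")) {
    fit$importance
  } else if (inherits(fit, "pmi_model")) {
    switch(fit$family,
      lasso = , enet = , ridge = abs(fit$std_coef),
      rf = fit$fit$importance,
      ann = {
        w1 <- fit$fit$weights[[1]]
        setNames(rowSums(abs(w1)), fit$features)
      },
      stop(sprintf("importance not defined for family '%s'", fit$family),
           call. = FALSE))
  } else {
    stop("unsupported model object", call. = FALSE)
  }
  raw <- pmax(raw, 0)
  if (sum(raw) == 0) raw <- rep(1, length(raw))
  raw / sum(raw)
}

#' Exact interventional Shapley values
#'
#' For every coalition `S` of features, the value `v(S)` is the mean model
#' prediction over the background rows with the features in `S` replaced
#' by the explained sample's values; Shapley values combine the marginal
#' contributions with the usual coalition weights. Exhaustive enumeration
#' (`2^p` coalitions) restricted to small panels; local accuracy
#' `sum(phi) = f(x) - E_bg f` holds by construction and is asserted.
#'
#' @param predict_fun function taking a feature matrix, returning
#'   predictions.
#' @param x numeric vector: the sample to explain (named or in background
#'   column order).
#' @param background matrix of background rows (the interventional
#'   reference distribution).
#' @param tol local-accuracy assertion tolerance.
#' @return named vector of Shapley values with the background expectation
#'   in `attr(, "base_value")`.
#' @export
exact_shapley <- function(predict_fun, x, background, tol = 1e-6) {
  background <- as.matrix(background)
  p <- ncol(background)
  if (p > 12) {
    stop("exact enumeration limited to <= 12 features; use a sampling ",
         "approximation for larger panels", call. = FALSE)
  }
  if (nrow(background) < 1) stop("empty background set", call. = FALSE)
  if (!is.null(names(x)) && !is.null(colnames(background))) {
    x <- x[colnames(background)]
  }
  n_s <- bitwShiftL(1L, p)
  nbg <- nrow(background)
  # one big prediction batch: 2^p blocks of the background with coalition
  # features swapped in
  big <- matrix(0, n_s * nbg, p, dimnames = list(NULL, colnames(background)))
  for (s in 0:(n_s - 1)) {
    blk <- background
    for (j in seq_len(p)) {
      if (bitwAnd(s, bitwShiftL(1L, j - 1L)) != 0L) blk[, j] <- x[j]
    }
    big[s * nbg + seq_len(nbg), ] <- blk
  }
  preds <- predict_fun(big)
  v <- vapply(0:(n_s - 1), function(s) mean(preds[s * nbg + seq_len(nbg)]),
              numeric(1))
  size <- vapply(0:(n_s - 1), function(s) sum(bitwAnd(s, bitwShiftL(1L, 0:(p - 1))) != 0),
                 numeric(1))
  wgt <- ifelse(size >= p, 0,  # full coalition never acts as S in phi_i
                factorial(size) * factorial(pmax(p - size - 1, 0)) /
                  factorial(p))
  phi <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(0:(n_s - 1), bit) == 0L)
    s0 <- without - 1L
    phi[j] <- sum(wgt[without] * (v[s0 + bit + 1L] - v[without]))
  }
  names(phi) <- colnames(background)
  base <- v[1]
  fx <- v[n_s]
  if (abs(sum(phi) - (fx - base)) > tol) {
    stop("Shapley local accuracy violated beyond tolerance", call. = FALSE)
  }
  attr(phi, "base_value") <- base
  phi
}

#' Shapley table for a set of samples
#'
#' @param predict_fun prediction function.
#' @param samples matrix of samples to explain.
#' @param background background matrix.
#' @return data.frame `sample`, `feature`, `phi`, `feature_value`.
#' @export
shapley_table <- function(predict_fun, samples, background) {
  samples <- as.matrix(samples)
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    phi <- exact_shapley(predict_fun, samples[i, ], background)
    data.frame(sample = rownames(samples)[i] %||% i,
               feature = names(phi), phi = as.numeric(phi),
               feature_value = as.numeric(samples[i, names(phi)]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
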