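# Model zoo behind the regression benchmarks: a uniform fit/predict
# interface over penalized linear models (glmnet), the compiled random
# forest, support-vector regression (e1071), two gradient-boosting
# configurations (xgboost linear and DART boosters), distance-weighted
# k-nearest neighbours, and a two-hidden-layer feed-forward network
# trained with Adam. Linear models and the network standardize features
# with training-fold statistics; tree and kernel models see raw features.

MODEL_FAMILIES <- c("lasso", "enet", "ridge", "rf", "knn", "svr_radial",
                    "svr_linear", "xgb_linear", "xgb_dart", "ann")

#' Seeded k-fold partition
#'
#' @param n number of samples.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return list of index vectors (the folds), a partition of `1:n`.
#' @export
cv_folds <- function(n, k, seed = 1) {
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  ids <- with_seed(seed, sample(n))
  unname(split(ids, rep(seq_len(k), length.out = n)))
}

#' Fit one regression model family
#'
#' @param x numeric feature matrix (samples x features).
#' @param y numeric response.
#' @param family one of `lasso`, `enet`, `ridge`, `rf`, `knn`,
#'   `svr_radial`, `svr_linear`, `xgb_linear`, `xgb_dart`, `ann`.
#' @param seed integer seed for stochastic families.
#' @param tune_folds inner CV folds for penalized linear models (`n` gives
#'   leave-one-out).
#' @param params optional list of family-specific overrides
#'   (`num_trees`, `mtry`, `min_split`, `min_leaf`, `k_neighbors`,
#'   `hidden`, `epochs`, `lr`, `nrounds`, `enet_alphas`).
#' @return object of class `pmi_model`.
#' @export
fit_model <- function(x, y, family, seed = 1, tune_folds = 10,
                      params = list()) {
  family <- match.arg(family, MODEL_FAMILIES)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite features or response", call. = FALSE)
  }
  obj <- list(family = family, features = colnames(x), params = params)

  if (family %in% c("lasso", "enet", "ridge", "ann")) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl == 0] <- 1
    xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
    obj$center <- ctr; obj$scale <- scl
  }

  if (family %in% c("lasso", "enet", "ridge")) {
    nf <- min(tune_folds, length(y))
    foldid <- with_seed(seed, sample(rep(seq_len(nf), length.out = length(y))))
    # explicit lambda grid reaching (numerically) zero regularization, so
    # the noiseless linear limit is attainable; glmnet's own path stops
    # early once the deviance saturates
    lmax <- max(abs(crossprod(xs, y - mean(y)))) / length(y)
    grid <- function(a) {
      exp(seq(log(lmax / max(a, 0.001) * 1.05), log(lmax * 1e-8),
              length.out = 100))
    }
    grouped <- length(y) / nf >= 3  # LOO-style folds need ungrouped CV
    if (family == "enet") {
      alphas <- params$enet_alphas %||% c(0.1, 0.3, 0.5, 0.7, 0.9)
      cvs <- lapply(alphas, function(a) {
        glmnet::cv.glmnet(xs, y, alpha = a, foldid = foldid,
                          standardize = FALSE, lambda = grid(a),
                          grouped = grouped)
      })
      best <- which.min(vapply(cvs, function(cv) min(cv$cvm), numeric(1)))
      cv <- cvs[[best]]
      obj$alpha <- alphas[best]
    } else {
      obj$alpha <- if (family == "lasso") 1 else 0
      cv <- glmnet::cv.glmnet(xs, y, alpha = obj$alpha, foldid = foldid,
                              standardize = FALSE, lambda = grid(obj$alpha),
                              grouped = grouped)
    }
    obj$fit <- cv
    obj$lambda <- cv$lambda.min
    co <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
    obj$std_coef <- setNames(co, colnames(x))
  } else if (family == "rf") {
    obj$fit <- rf_regress(
      x, y,
      num_trees = params$num_trees %||% 500,
      mtry = params$mtry %||% "sqrt",
      min_split = params$min_split %||% 2,
      min_leaf = params$min_leaf %||% 1,
      seed = seed)
  } else if (family == "knn") {
    obj$fit <- list(x = x, y = y, k = params$k_neighbors %||% 3)
  } else if (family %in% c("svr_radial", "svr_linear")) {
    obj$fit <- e1071::svm(
      x, y, kernel = if (family == "svr_radial") "radial" else "linear",
      type = "eps-regression")
  } else if (family == "xgb_linear") {
    obj$fit <- xgboost::xgboost(
      x, y, booster = "gblinear", nrounds = params$nrounds %||% 100,
      nthreads = 1, seed = seed %% 2147483647, verbosity = 0)
  } else if (family == "xgb_dart") {
    obj$fit <- xgboost::xgboost(
      x, y, booster = "dart", max_depth = 3, learning_rate = 0.1,
      rate_drop = 0.1, nrounds = params$nrounds %||% 150,
      nthreads = 1, seed = seed %% 2147483647, verbosity = 0)
  } else if (family == "ann") {
    obj$fit <- mlp_fit(xs, y,
                       hidden = params$hidden %||% c(50, 20),
                       epochs = params$epochs %||% 2000,
                       lr = params$lr %||% 1e-3,
                       seed = seed)
  }
  class(obj) <- "pmi_model"
  obj
}

#' @param object a `pmi_model`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @rdname fit_model
#' @export
predict.pmi_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    newdata <- newdata[, object$features, drop = FALSE]
  }
  if (!is.null(object$center)) {
    newdata <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  }
  switch(object$family,
    lasso = , enet = , ridge =
      as.numeric(predict(object$fit, newx = newdata, s = "lambda.min")),
    rf = predict(object$fit, newdata),
    knn = knn_predict(object$fit, newdata),
    svr_radial = , svr_linear = as.numeric(predict(object$fit, newdata)),
    xgb_linear = , xgb_dart = as.numeric(predict(object$fit, newdata)),
    ann = mlp_predict(object$fit, newdata))
}

knn_predict <- function(fit, newdata) {
  apply(newdata, 1, function(q) {
    d <- sqrt(colSums((t(fit$x) - q)^2))
    nn <- order(d)[seq_len(min(fit$k, length(d)))]
    dz <- d[nn]
    if (any(dz == 0)) return(mean(fit$y[nn[dz == 0]]))
    w <- 1 / dz
    sum(w * fit$y[nn]) / sum(w)
  })
}

# Two-hidden-layer ReLU network trained with full-batch Adam on squared
# error. The response is standardized internally and predictions mapped
# back; features are expected pre-standardized by the caller.
mlp_fit <- function(x, y, hidden = c(50, 20), epochs = 2000, lr = 1e-3,
                    seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  y_ctr <- mean(y); y_scl <- sd(y); if (y_scl == 0) y_scl <- 1
  yt <- (y - y_ctr) / y_scl
  sizes <- c(p, hidden, 1)
  L <- length(sizes) - 1
  W <- list(); b <- list()
  with_seed(seed, {
    for (l in seq_len(L)) {
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1],
                             sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
  })
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  relu <- function(a) pmax(a, 0)
  for (t in seq_len(epochs)) {
    a <- list(x)
    z <- list()
    for (l in seq_len(L)) {
      z[[l]] <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
      a[[l + 1]] <- if (l < L) relu(z[[l]]) else z[[l]]
    }
    delta <- 2 * (a[[L + 1]] - yt) / n
    for (l in rev(seq_len(L))) {
      gW <- crossprod(a[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(W[[l]])) * (z[[l - 1]] > 0)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      mhW <- mW[[l]] / (1 - beta1^t); vhW <- vW[[l]] / (1 - beta2^t)
      mhb <- mb[[l]] / (1 - beta1^t); vhb <- vb[[l]] / (1 - beta2^t)
      W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
      b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
  }
  list(weights = W, biases = b, y_center = y_ctr, y_scale = y_scl,
       hidden = hidden)
}

mlp_predict <- function(fit, x) {
  a <- as.matrix(x)
  L <- length(fit$weights)
  for (l in seq_len(L)) {
    a <- sweep(a %*% fit$weights[[l]], 2, fit$biases[[l]], "+")
    if (l < L) a <- pmax(a, 0)
  }
  as.numeric(a) * fit$y_scale + fit$y_center
}

#' Cross-validated regression with pooled out-of-fold metrics
#'
#' Runs seeded k-fold cross-validation for one model family, pools the
#' out-of-fold predictions (one per sample) and computes `R^2`, MAE and
#' RMSE on the pooled vector; per-fold metrics are also reported. A final
#' model is fitted on the full data for importance / attribution.
#'
#' @inheritParams fit_model
#' @param k number of folds.
#' @return object of class `pmi_cv`: `family`, `predictions` (data.frame
#'   `sample`, `y`, `y_hat`, `fold`), `metrics` (pooled), `fold_metrics`,
#'   `full_fit`, `importance`.
#' @export
cv_regress <- function(x, y, family, k = 10, seed = 1, tune_folds = 10,
                       params = list()) {
  x <- as.matrix(x)
  n <- nrow(x)
  folds <- cv_folds(n, k, seed = seed)
  y_hat <- rep(NA_real_, n)
  fold_id <- rep(NA_integer_, n)
  fold_metrics <- vector("list", k)
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    fit <- fit_model(x[-test, , drop = FALSE], y[-test], family,
                     seed = seed + f, tune_folds = tune_folds,
                     params = params)
    y_hat[test] <- predict(fit, x[test, , drop = FALSE])
    fold_id[test] <- f
    fold_metrics[[f]] <- tryCatch(
      regression_metrics(y[test], y_hat[test]),
      error = function(e) c(r_squared = NA, mae = mean(abs(y[test] - y_hat[test])),
                            rmse = sqrt(mean((y[test] - y_hat[test])^2))))
  }
  full_fit <- fit_model(x, y, family, seed = seed, tune_folds = tune_folds,
                        params = params)
  imp <- tryCatch(normalized_importance(full_fit), error = function(e) NULL)
  structure(list(
    family = family,
    predictions = data.frame(
      sample = rownames(x) %||% seq_len(n), y = y, y_hat = y_hat,
      fold = fold_id, stringsAsFactors = FALSE),
    metrics = regression_metrics(y, y_hat),
    fold_metrics = do.call(rbind, fold_metrics),
    full_fit = full_fit, importance = imp, k = k, seed = seed),
    class = "pmi_cv")
}

#' @export
print.pmi_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("%s: %d-fold CV  R2 = %.3f  MAE = %.3f  RMSE = %.3f\n",
              x$family, x$k, m["r_squared"], m["mae"], m["rmse"]))
  invisible(x)
}
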