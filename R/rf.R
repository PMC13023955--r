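#' Random-forest regression (compiled, small-sample oriented)
#'
#' A regression random forest with the conventions of the scikit-learn
#' `RandomForestRegressor`: bootstrap resampling, `mtry` features drawn
#' without replacement at every split, exhaustive variance-reduction split
#' search with midpoint thresholds, `min_split` / `min_leaf` stopping, and
#' impurity-decrease feature importance. The implementation is compiled and
#' tuned for the very small design matrices that the multi-seed stability
#' selection procedures refit tens of thousands of times.
#'
#' @param x numeric matrix (samples x features) with column names.
#' @param y numeric response vector.
#' @param num_trees number of trees.
#' @param mtry features tried per split: `"sqrt"` (`floor(sqrt(p))`),
#'   `"all"`, or an integer.
#' @param min_split minimum node size to attempt a split.
#' @param min_leaf minimum samples in each child.
#' @param seed integer seed for the forest's own RNG (independent of R's).
#' @return an object of class `pmi_rf` with elements `forest`, `importance`
#'   (raw mean impurity decrease per feature) and `features`.
#' @examples
#' x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
#' y <- x[, 1] + rnorm(50, sd = 0.1)
#' fit <- rf_regress(x, y, num_trees = 100, seed = 1)
#' cor(predict(fit, x), y)
#' @export
rf_regress <- function(x, y, num_trees = 500, mtry = "sqrt", min_split = 2,
                       min_leaf = 1, seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.double(y)
  if (anyNA(x) || anyNA(y)) stop("non-finite values in x or y", call. = FALSE)
  p <- ncol(x)
  m <- if (identical(mtry, "sqrt")) {
    max(1L, floor(sqrt(p)))
  } else if (identical(mtry, "all")) {
    p
  } else {
    as.integer(mtry)
  }
  forest <- .rf_fit_cpp(x, y, as.integer(num_trees), as.integer(m),
                        as.integer(min_split), as.integer(min_leaf),
                        as.double(seed))
  structure(
    list(forest = forest,
         importance = setNames(forest$importance, colnames(x)),
         features = colnames(x),
         num_trees = num_trees, mtry = m,
         min_split = min_split, min_leaf = min_leaf),
    class = "pmi_rf")
}

#' @param object a `pmi_rf` fit.
#' @param newdata numeric matrix with at least the training features.
#' @param ... unused.
#' @rdname rf_regress
#' @export
predict.pmi_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata))) {
    newdata <- newdata[, object$features, drop = FALSE]
  }
  storage.mode(newdata) <- "double"
  .rf_predict_cpp(object$forest, newdata)
}

#' @export
print.pmi_rf <- function(x, ...) {
  cat(sprintf("Random forest regression: %d trees, mtry = %d, %d features\n",
              x$num_trees, x$mtry, length(x$features)))
  invisible(x)
}
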