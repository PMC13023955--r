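# Class-level time-course testing (Student's t + BH) and feature-level
# fuzzy c-means temporal clustering with peak assignment.

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin, validating wrapper around the standard step-up procedure
#' (`p.adjust(method = "BH")`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, matched by index.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be finite numbers in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Per-class RPM time-course tests against baseline
#'
#' For every sncRNA class and non-baseline time point, a two-sided
#' equal-variance two-sample t-test of per-replicate class-total RPM
#' against the baseline time point, with BH correction applied jointly
#' across all (class, timepoint) tests.
#'
#' @param class_rpm data.frame with columns `class`, `sample_id`,
#'   `timepoint`, `rpm` (per-replicate class totals; see
#'   [class_rpm_table()]).
#' @param baseline baseline time point (default 0).
#' @param welch use Welch's unequal-variance test instead of Student's.
#' @return data.frame `class`, `timepoint`, `mean_rpm`, `mean_rpm_baseline`,
#'   `t`, `p`, `q`, `stars`.
#' @export
class_timecourse_test <- function(class_rpm, baseline = 0, welch = FALSE) {
  stopifnot(all(c("class", "timepoint", "rpm") %in% names(class_rpm)))
  cls <- sort(unique(class_rpm$class))
  tps <- setdiff(sort(unique(class_rpm$timepoint)), baseline)
  rows <- list()
  for (cl in cls) {
    base <- class_rpm$rpm[class_rpm$class == cl &
                            class_rpm$timepoint == baseline]
    if (length(base) < 2) stop("need >= 2 replicates at baseline",
                               call. = FALSE)
    for (tp in tps) {
      x <- class_rpm$rpm[class_rpm$class == cl & class_rpm$timepoint == tp]
      if (length(x) < 2) stop("need >= 2 replicates per time point",
                              call. = FALSE)
      if (sd(x) == 0 && sd(base) == 0 && mean(x) == mean(base)) {
        tt <- list(statistic = 0, p.value = 1)
      } else {
        tt <- t.test(x, base, var.equal = !welch)
      }
      rows[[length(rows) + 1]] <- data.frame(
        class = cl, timepoint = tp, mean_rpm = mean(x),
        mean_rpm_baseline = mean(base),
        t = unname(tt$statistic), p = unname(tt$p.value),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$stars <- cut(out$q, c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  out
}

#' Per-replicate class-total RPM long table
#'
#' Convenience reshaper from a [build_count_matrix()] result plus sample
#' metadata to the long format consumed by [class_timecourse_test()].
#'
#' @param cm result of [build_count_matrix()].
#' @param sample_timepoints named numeric vector: time point per sample id.
#' @return data.frame `class`, `sample_id`, `timepoint`, `rpm`.
#' @export
class_rpm_table <- function(cm, sample_timepoints) {
  rpm <- cm$rpm
  cls <- cm$feature_class[rownames(rpm)]
  keep <- cls != "unmapped"
  agg <- rowsum(rpm[keep, , drop = FALSE], cls[keep])
  out <- data.frame(
    class = rep(rownames(agg), ncol(agg)),
    sample_id = rep(colnames(agg), each = nrow(agg)),
    rpm = as.vector(agg), stringsAsFactors = FALSE)
  out$timepoint <- unname(sample_timepoints[out$sample_id])
  out
}

#' Standardize feature profiles over time
#'
#' Replicates are averaged per time point, then each feature's profile is
#' centred and scaled to mean 0 / sd 1 across time points (the usual
#' pre-processing before soft temporal clustering; the population
#' denominator `n` is used, so a three-point profile 0,1,2 maps to
#' -1.2247, 0, 1.2247). Features with zero standard deviation across time
#' points are excluded and reported.
#'
#' @param rpm features x samples RPM matrix.
#' @param sample_timepoints named numeric vector: time point per sample id.
#' @return matrix features x timepoints of z-profiles; excluded feature ids
#'   in `attr(, "excluded")`.
#' @export
standardize_profiles <- function(rpm, sample_timepoints) {
  tp <- sample_timepoints[colnames(rpm)]
  tps <- sort(unique(tp))
  if (length(tps) < 2) stop("need >= 2 time points", call. = FALSE)
  prof <- sapply(tps, function(t) {
    rowMeans(rpm[, tp == t, drop = FALSE])
  })
  colnames(prof) <- tps
  ctr <- rowMeans(prof)
  sds <- sqrt(rowMeans((prof - ctr)^2))  # population denominator
  excluded <- rownames(prof)[sds == 0]
  keep <- sds > 0
  z <- (prof[keep, , drop = FALSE] - ctr[keep]) / sds[keep]
  attr(z, "excluded") <- excluded
  z
}

#' Fuzzy c-means clustering of temporal profiles
#'
#' Standard FCM alternating optimization: memberships
#' `u_ij = 1 / sum_k (d_ij / d_kj)^(2/(m-1))` with Euclidean distance, and
#' centers as the `u^m`-weighted means, iterated until the relative drop in
#' the objective `J = sum u_ij^m d_ij^2` falls below `tol`. Centers are
#' initialized from `c` distinct randomly selected profiles (seeded).
#' Profiles exactly coinciding with a center receive hard membership.
#'
#' @param z features x timepoints matrix (typically z-profiles).
#' @param c number of clusters.
#' @param m fuzzifier (> 1).
#' @param tol relative convergence tolerance on the objective.
#' @param max_iter iteration cap.
#' @param seed seed for center initialization.
#' @return object of class `pmi_fcm`: `membership` (features x c),
#'   `centers` (c x T), `m`, `objective` (per-iteration trajectory).
#' @export
fcm_cluster <- function(z, c = 6, m = 2, tol = 1e-6, max_iter = 200,
                        seed = 1) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (c > n) stop("more clusters than features", call. = FALSE)
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)
  centers <- with_seed(seed, z[sample(n, c), , drop = FALSE])
  # perturb coinciding initial centers so they are distinct
  dup <- duplicated(centers)
  if (any(dup)) {
    centers[dup, ] <- centers[dup, ] +
      with_seed(seed + 1, matrix(rnorm(sum(dup) * ncol(z), 0, 1e-6),
                                 nrow = sum(dup)))
  }
  obj <- numeric(0)
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(z^2), rep(1, c)) +
      outer(rep(1, n), rowSums(centers^2)) - 2 * z %*% t(centers)
    d2 <- pmax(d2, 0)
    u <- matrix(0, n, c)
    zero <- d2 < 1e-300
    has_zero <- rowSums(zero) > 0
    if (any(has_zero)) {
      u[has_zero, ] <- zero[has_zero, , drop = FALSE] /
        rowSums(zero[has_zero, , drop = FALSE])
    }
    if (any(!has_zero)) {
      dm <- d2[!has_zero, , drop = FALSE]^(-1 / (m - 1))
      u[!has_zero, ] <- dm / rowSums(dm)
    }
    obj <- c(obj, sum(u^m * d2))
    um <- u^m
    centers <- (t(um) %*% z) / colSums(um)
    if (it > 1 && abs(obj[it - 1] - obj[it]) <=
          tol * max(obj[it - 1], .Machine$double.eps)) break
  }
  rownames(u) <- rownames(z)
  rownames(centers) <- paste0("cluster", seq_len(c))
  colnames(u) <- rownames(centers)
  structure(list(membership = u, centers = centers, m = m,
                 objective = obj, iterations = length(obj)),
            class = "pmi_fcm")
}

#' Summarize a fuzzy clustering
#'
#' Hard-assigns features by maximal membership, reports each cluster's peak
#' time point (argmax of its center profile) and its share of features.
#'
#' @param fcm a [fcm_cluster()] result.
#' @return data.frame `cluster`, `n_features`, `percent`, `peak_timepoint`.
#' @export
cluster_summary <- function(fcm) {
  hard <- apply(fcm$membership, 1, which.max)
  k <- nrow(fcm$centers)
  n_feat <- tabulate(hard, nbins = k)
  idx <- apply(fcm$centers, 1, which.max)
  tp <- suppressWarnings(as.numeric(colnames(fcm$centers)))
  peaks <- if (length(tp) && !anyNA(tp)) tp[idx] else idx
  data.frame(
    cluster = rownames(fcm$centers),
    n_features = n_feat,
    percent = 100 * n_feat / sum(n_feat),
    peak_timepoint = peaks,
    stringsAsFactors = FALSE)
}

#' @export
print.pmi_fcm <- function(x, ...) {
  cat(sprintf("Fuzzy c-means: %d features, %d clusters, m = %g, %d iterations\n",
              nrow(x$membership), nrow(x$centers), x$m, x$iterations))
  invisible(x)
}
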