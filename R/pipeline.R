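#' Split trials into fixed-length windows
#'
#' Non-overlapping, contiguous windows from each trial's start; a trailing
#' remainder shorter than one window is dropped (logged). Each window
#' inherits its trial's label and subject.
#'
#' @param trials A `"fewt_trialset"`.
#' @param window_seconds Window length in seconds.
#' @return List of windows; each has `data` (samples x channels matrix),
#'   `label`, `subject`, `trial`, `window`.
#' @export
segment_trials <- function(trials, window_seconds) {
  if (!inherits(trials, "fewt_trialset")) stop("`trials` must be a trial set", call. = FALSE)
  stopifnot_scalar_number(window_seconds, "window_seconds", positive = TRUE)
  wlen <- as.integer(round(window_seconds * trials$rate))
  if (wlen < 8L) stop("window must hold at least 8 samples", call. = FALSE)
  out <- list()
  dropped_any <- FALSE
  for (ti in seq_along(trials$trials)) {
    tr <- trials$trials[[ti]]
    n <- nrow(tr$data)
    if (wlen > n) {
      stop(sprintf("window of %d samples longer than trial %d (%d samples)",
                   wlen, ti, n), call. = FALSE)
    }
    nw <- n %/% wlen
    if (n %% wlen > 0L) dropped_any <- TRUE
    for (w in seq_len(nw)) {
      rows <- ((w - 1L) * wlen + 1L):(w * wlen)
      out[[length(out) + 1L]] <- list(
        data = tr$data[rows, , drop = FALSE],
        label = tr$label, subject = tr$subject, trial = ti, window = w
      )
    }
  }
  if (dropped_any) fewt_log("trailing remainder shorter than one window dropped")
  out
}

stratified_folds <- function(labels, folds, seed) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < folds)) {
    stop(sprintf(
      "cannot stratify %d folds with class counts: %s",
      folds, paste(names(counts), counts, sep = "=", collapse = ", ")
    ), call. = FALSE)
  }
  assign <- integer(length(labels))
  with_seed(seed, {
    for (k in names(counts)) {
      idx <- which(labels == k)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

# mean held-out accuracy of an (C, gamma) cell under an inner CV on the
# training rows
inner_cv_accuracy <- function(x, y, C, gamma, inner_assign) {
  correct <- 0L
  for (f in sort(unique(inner_assign))) {
    tr <- inner_assign != f
    fit <- svc_fit(x[tr, , drop = FALSE], y[tr], C = C, gamma = gamma)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Cross-validated classification accuracy
#'
#' Stratified k-fold cross-validation of the Gaussian-kernel SVC, with C and
#' the kernel width grid-searched inside each training fold (leak-free
#' nested search), on either the full feature set (`ranked = NULL`, the
#' "without feature selection" condition) or on growing prefixes of a
#' ranked feature list. Features are standardized with training-fold
#' statistics. The reported accuracy is the maximum of the per-k curve.
#'
#' @param features A [feature_matrix()].
#' @param ranked Optional [forward_select()] result.
#' @param folds Outer folds (default 10).
#' @param grid List with numeric vectors `C` and `gamma`
#'   (defaults `10^(-2:3)` and `10^(-4:1)`).
#' @param seed Integer seed for fold assignment.
#' @param k_values Which prefix sizes of the ranking to evaluate; default
#'   all of `1..length(ranked)`. Ignored when `ranked` is `NULL`.
#' @param inner_folds Folds of the inner grid-search CV (default 3).
#' @return List with `curve` (data frame `k`, `accuracy` in percent),
#'   `accuracy` (max over the curve), `best_k`.
#' @export
crossval_classify <- function(features, ranked = NULL, folds = 10L,
                              grid = list(C = 10^(-2:3), gamma = 10^(-4:1)),
                              seed = 1L, k_values = NULL, inner_folds = 3L) {
  stopifnot(inherits(features, "fewt_features"))
  x <- features$x
  y <- as.character(features$labels)
  folds <- as.integer(folds)
  if (is.null(ranked)) {
    k_values <- ncol(x)
    col_sets <- list(seq_len(ncol(x)))
  } else {
    idx <- ranked$ranked_indices
    if (is.null(k_values)) k_values <- seq_along(idx)
    k_values <- as.integer(k_values)
    if (any(k_values < 1L | k_values > length(idx))) {
      stop("`k_values` outside the ranking length", call. = FALSE)
    }
    col_sets <- lapply(k_values, function(k) idx[seq_len(k)])
  }
  outer_assign <- stratified_folds(y, folds, child_seed(seed, 1))

  acc <- numeric(length(col_sets))
  for (ci in seq_along(col_sets)) {
    cols <- col_sets[[ci]]
    xs <- x[, cols, drop = FALSE]
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- outer_assign != f
      mu <- colMeans(xs[tr, , drop = FALSE])
      sdv <- apply(xs[tr, , drop = FALSE], 2L, stats::sd)
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      xtr <- sweep(sweep(xs[tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
      xte <- sweep(sweep(xs[!tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
      ytr <- y[tr]
      inner_assign <- stratified_folds(ytr, inner_folds,
                                       child_seed(seed, 100 + f))
      best <- NULL
      for (C in grid$C) {
        for (g in grid$gamma) {
          a <- inner_cv_accuracy(xtr, ytr, C, g, inner_assign)
          if (is.null(best) || a > best$a) best <- list(a = a, C = C, g = g)
        }
      }
      fit <- svc_fit(xtr, ytr, C = best$C, gamma = best$g)
      pred <- predict(fit, xte)
      correct <- correct + sum(pred == y[!tr])
    }
    acc[ci] <- 100 * correct / length(y)
  }
  curve <- data.frame(k = k_values, accuracy = acc)
  list(curve = curve, accuracy = max(acc), best_k = curve$k[which.max(acc)])
}

#' Percentage-gain ranking of method combinations
#'
#' For each task pair the baseline reference is the maximum accuracy the
#' baseline extraction family reaches over all of its selection variants
#' (including "WFS", no selection). Each test-family combination's per-task
#' percentage gain is `100 * (a - a_max) / a_max`; gains are averaged over
#' task pairs and ranked so that a larger average gain receives a smaller
#' rank (equal gains share a rank).
#'
#' @param acc Data frame with columns `task_pair`, `extraction`,
#'   `selection`, `accuracy` (percent; multiple rows per cell, e.g.
#'   subjects, are averaged).
#' @param baseline_family Extraction id of the baseline (default `"EWT"`).
#' @param test_family Extraction id being ranked (default `"FEWT"`).
#' @return Data frame with columns `combination`, `gain`, `rank`, of class
#'   `"fewt_ranking"`.
#' @export
percentage_gain_rank <- function(acc, baseline_family = "EWT",
                                 test_family = "FEWT") {
  need <- c("task_pair", "extraction", "selection", "accuracy")
  if (!all(need %in% names(acc))) {
    stop("accuracy table needs columns task_pair, extraction, selection, accuracy",
         call. = FALSE)
  }
  if (any(acc$accuracy < 0 | acc$accuracy > 100)) {
    stop("accuracies must lie in [0, 100]", call. = FALSE)
  }
  cell <- stats::aggregate(
    accuracy ~ task_pair + extraction + selection, data = acc, FUN = mean
  )
  tasks <- unique(cell$task_pair)
  base <- cell[cell$extraction == baseline_family, ]
  test <- cell[cell$extraction == test_family, ]
  if (!nrow(base) || !nrow(test)) stop("both families must be present", call. = FALSE)
  sels <- sort(unique(test$selection))
  gains <- matrix(NA_real_, length(tasks), length(sels),
                  dimnames = list(tasks, sels))
  for (t in tasks) {
    bt <- base[base$task_pair == t, ]
    if (!nrow(bt)) stop(sprintf("baseline family missing for task pair '%s'", t), call. = FALSE)
    amax <- max(bt$accuracy)
    if (amax == 0) stop(sprintf("baseline maximum is 0 for task pair '%s'", t), call. = FALSE)
    for (s in sels) {
      a <- test$accuracy[test$task_pair == t & test$selection == s]
      if (!length(a)) stop(sprintf("missing cell: task '%s', selection '%s'", t, s), call. = FALSE)
      gains[t, s] <- (a - amax) / amax * 100
    }
  }
  gain <- colMeans(gains)
  out <- data.frame(
    combination = paste(sels, test_family, sep = "_"),
    gain = as.numeric(gain),
    rank = rank(-gain, ties.method = "average"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("fewt_ranking", class(out))
  out
}

#' Friedman rank test over blocks
#'
#' Within each block the combinations are ranked by accuracy (best = rank 1,
#' ties get average ranks); mean ranks, the tie-corrected Friedman
#' chi-square statistic and its p-value are reported, with a reject/retain
#' decision at the given significance level. If accuracies are constant
#' within every block the statistic is undefined and the null is retained
#' with a diagnostic.
#'
#' @param acc Numeric matrix, blocks x combinations.
#' @param alpha Significance level (default 0.05).
#' @return List with `mean_ranks`, `statistic`, `df`, `p_value`,
#'   `decision` (`"reject"` or `"retain"`), `alpha`.
#' @export
friedman_rank <- function(acc, alpha = 0.05) {
  acc <- as.matrix(acc)
  b <- nrow(acc); k <- ncol(acc)
  if (b < 2L || k < 2L) stop("need at least 2 blocks and 2 combinations", call. = FALSE)
  r <- t(apply(acc, 1L, function(row) rank(-row)))  # best = 1
  mean_ranks <- colMeans(r)
  ties <- apply(r, 1L, function(row) {
    tab <- table(row)
    sum(tab^3 - tab)
  })
  denom <- b * k * (k + 1) - sum(ties) / (k - 1)
  if (denom <= 0) {
    fewt_log("accuracies constant within every block; Friedman statistic undefined")
    return(list(
      mean_ranks = mean_ranks, statistic = NA_real_, df = k - 1L,
      p_value = NA_real_, decision = "retain", alpha = alpha
    ))
  }
  stat <- 12 * sum((colSums(r) - b * (k + 1) / 2)^2) / denom
  p <- stats::pchisq(stat, df = k - 1L, lower.tail = FALSE)
  list(
    mean_ranks = mean_ranks, statistic = stat, df = k - 1L, p_value = p,
    decision = if (p < alpha) "reject" else "retain", alpha = alpha
  )
}
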