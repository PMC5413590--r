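#' Per-class Gaussian summary statistics
#'
#' Sample means, unbiased sample covariances, empirical priors `n_i / n`,
#' and the global mean for a (possibly column-restricted) feature matrix.
#'
#' @param x Numeric matrix (rows = samples) or vector (one feature).
#' @param labels Class label per row.
#' @return Object of class `"fewt_class_stats"` with `means` (class x dim),
#'   `covariances` (list), `priors`, `global_mean`, `classes`, `n`.
#' @export
class_statistics <- function(x, labels) {
  x <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("one label per row required", call. = FALSE)
  cls <- sort(unique(labels))
  counts <- vapply(cls, function(k) sum(labels == k), numeric(1))
  if (any(counts < 2)) stop("need at least 2 samples per class", call. = FALSE)
  means <- do.call(rbind, lapply(cls, function(k) {
    colMeans(x[labels == k, , drop = FALSE])
  }))
  rownames(means) <- cls
  covs <- lapply(cls, function(k) stats::cov(x[labels == k, , drop = FALSE]))
  names(covs) <- cls
  structure(
    list(
      means = means, covariances = covs, priors = counts / nrow(x),
      global_mean = colMeans(x), classes = cls, n = nrow(x)
    ),
    class = "fewt_class_stats"
  )
}

# Regularize class covariances when the beta-pooled matrix is numerically
# singular; returns the (possibly ridged) covariance list.
ridge_covs <- function(stats, beta, ridge) {
  s1 <- stats$covariances[[1L]]
  s2 <- stats$covariances[[2L]]
  pooled <- (1 - beta) * s1 + beta * s2
  needs <- tryCatch(kappa(pooled, exact = FALSE) > 1e12 ||
                      !is.finite(determinant(pooled)$modulus),
                    error = function(e) TRUE)
  if (needs) {
    if (ridge <= 0) ridge <- 1e-6 * mean(diag(pooled))
    if (ridge <= 0) ridge <- 1e-12
    fewt_log(sprintf("near-singular covariance; applying ridge %.3g", ridge))
    eye <- diag(nrow(pooled))
    s1 <- s1 + ridge * eye
    s2 <- s2 + ridge * eye
  }
  list(s1 = s1, s2 = s2)
}

logdet <- function(m) {
  d <- determinant(m, logarithm = TRUE)
  if (d$sign <= 0) stop("covariance with non-positive determinant", call. = FALSE)
  as.numeric(d$modulus)
}

#' Chernoff distance between two Gaussian class summaries
#'
#' `J_c = (1/2) beta (1-beta) dmu' S_beta^{-1} dmu
#'        + (1/2) log(|S_beta| / (|S1|^{1-beta} |S2|^beta))`
#' with `S_beta = (1-beta) S1 + beta S2`. At `beta = 1/2` this is the
#' Bhattacharyya distance. Covariances are ridge-regularized only when the
#' pooled matrix is numerically singular (condition number above 1e12),
#' because the log-determinant term needs proper determinants.
#'
#' @param stats A two-class [class_statistics()].
#' @param beta Mixing weight in `(0, 1)`.
#' @param ridge Ridge added to each covariance diagonal when regularization
#'   triggers; `0` (default) picks `1e-6 * mean(diag)`.
#' @return A single non-negative number.
#' @export
chernoff_distance <- function(stats, beta = 0.5, ridge = 0) {
  if (!inherits(stats, "fewt_class_stats")) stop("`stats` required", call. = FALSE)
  if (length(stats$classes) != 2L) {
    stop("Chernoff/Bhattacharyya distance is a two-class measure", call. = FALSE)
  }
  if (beta <= 0 || beta >= 1) stop("`beta` must lie in (0, 1)", call. = FALSE)
  cv <- ridge_covs(stats, beta, ridge)
  dmu <- stats$means[2L, ] - stats$means[1L, ]
  pooled <- (1 - beta) * cv$s1 + beta * cv$s2
  quad <- tryCatch(
    as.numeric(crossprod(dmu, solve(pooled, dmu))),
    error = function(e) stop("pooled covariance singular even after ridge", call. = FALSE)
  )
  0.5 * beta * (1 - beta) * quad +
    0.5 * (logdet(pooled) - (1 - beta) * logdet(cv$s1) - beta * logdet(cv$s2))
}

#' Bhattacharyya distance
#'
#' Chernoff distance at `beta = 1/2`:
#' `J_B = (1/8) dmu' ((S1 + S2)/2)^{-1} dmu
#'        + (1/2) log(|(S1 + S2)/2| / sqrt(|S1| |S2|))`.
#'
#' @inheritParams chernoff_distance
#' @return A single non-negative number.
#' @export
bhattacharyya_distance <- function(stats, ridge = 0) {
  chernoff_distance(stats, beta = 0.5, ridge = ridge)
}

#' Scatter-matrix trace-ratio criterion
#'
#' `J_SR = trace(S_b) / trace(S_w)` with the prior-weighted within-class
#' scatter `S_w = sum_i P_i E[(x - mu_i)(x - mu_i)']` and between-class
#' scatter `S_b = sum_i P_i (mu_i - mu_0)(mu_i - mu_0)'`. Large values mean
#' compact classes with separated means.
#'
#' @param x Numeric matrix or vector of feature values.
#' @param labels Class label per row.
#' @return A single non-negative number.
#' @export
scatter_ratio <- function(x, labels) {
  x <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2L) stop("need at least 2 classes", call. = FALSE)
  mu0 <- colMeans(x)
  tw <- 0; tb <- 0
  for (k in cls) {
    xi <- x[labels == k, , drop = FALSE]
    pi_k <- nrow(xi) / nrow(x)
    mui <- colMeans(xi)
    tw <- tw + pi_k * mean(rowSums(sweep(xi, 2L, mui)^2))
    tb <- tb + pi_k * sum((mui - mu0)^2)
  }
  if (tw <= 0) stop("zero within-class scatter: every point equals its class mean", call. = FALSE)
  tb / tw
}

#' Linear-regression criterion
#'
#' Coefficient of determination of the least-squares fit (with intercept)
#' of the numeric class target on the feature columns:
#' `J_LR = 1 - SSE / SSTO`, guaranteed in `[0, 1]`. Class labels are coded
#' `0, 1, ...` in sorted label order. Rank-deficient designs are fitted via
#' the pivoted QR (logged); a constant target is rejected.
#'
#' @param x Numeric matrix or vector of feature values.
#' @param labels Class labels (coded to numeric) or a numeric target.
#' @return A single number in `[0, 1]`.
#' @export
lr_criterion <- function(x, labels) {
  x <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
  y <- if (is.numeric(labels)) as.numeric(labels) else {
    cls <- sort(unique(as.character(labels)))
    as.numeric(match(as.character(labels), cls) - 1L)
  }
  n <- nrow(x)
  if (length(y) != n) stop("one target per row required", call. = FALSE)
  ssto <- sum((y - mean(y))^2)
  if (ssto <= 0) stop("constant target: SSTO = 0", call. = FALSE)
  if (n <= ncol(x) + 1L) stop("need more samples than fitted coefficients", call. = FALSE)
  design <- cbind(1, x)
  fit <- stats::lm.fit(design, y)
  if (fit$rank < ncol(design)) fewt_log("rank-deficient design in LR criterion")
  sse <- sum(fit$residuals^2)
  max(0, min(1, 1 - sse / ssto))
}

criterion_fun <- function(criterion_name, ridge = 0) {
  switch(
    match.arg(criterion_name, c("bd", "sr", "lr")),
    bd = function(x, labels) bhattacharyya_distance(class_statistics(x, labels), ridge = ridge),
    sr = function(x, labels) scatter_ratio(x, labels),
    lr = function(x, labels) lr_criterion(x, labels)
  )
}

#' Greedy forward feature selection
#'
#' Incrementally includes features one by one: at each step the candidate
#' whose inclusion maximizes the multivariate criterion on the current
#' subset is added (ties broken towards the lower column index). Candidates
#' on which the criterion fails (e.g. a singular class covariance under BD)
#' are skipped; if every remaining candidate fails, the partial ranking is
#' returned with a logged reason.
#'
#' @param features A [feature_matrix()] or numeric matrix.
#' @param labels Class labels (taken from the feature matrix when omitted).
#' @param criterion_name One of `"bd"`, `"sr"`, `"lr"`.
#' @param k Number of features to rank (default 25).
#' @param ridge Passed to the BD criterion.
#' @return Object of class `"fewt_selection"`: `ranked_indices`,
#'   `criterion_trace`, `criterion_name`, `k`, `column_names`.
#' @export
forward_select <- function(features, labels = NULL, criterion_name = "lr",
                           k = 25L, ridge = 0) {
  if (inherits(features, "fewt_features")) {
    labels <- labels %||% features$labels
    x <- features$x
  } else {
    x <- as.matrix(features)
  }
  if (is.null(labels)) stop("`labels` required", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > ncol(x)) stop("`k` must lie in 1..ncol", call. = FALSE)
  crit <- criterion_fun(criterion_name, ridge)

  chosen <- integer(0)
  trace <- numeric(0)
  remaining <- seq_len(ncol(x))
  while (length(chosen) < k && length(remaining)) {
    vals <- rep(NA_real_, length(remaining))
    for (i in seq_along(remaining)) {
      cols <- c(chosen, remaining[i])
      vals[i] <- tryCatch(
        suppressMessages(crit(x[, cols, drop = FALSE], labels)),
        error = function(e) NA_real_
      )
    }
    if (all(is.na(vals))) {
      fewt_log(sprintf(
        "criterion '%s' failed on every remaining candidate after %d inclusions; stopping early",
        criterion_name, length(chosen)
      ))
      break
    }
    best <- which.max(vals)     # first max: lower column index wins ties
    chosen <- c(chosen, remaining[best])
    trace <- c(trace, vals[best])
    remaining <- remaining[-best]
  }
  structure(
    list(
      ranked_indices = chosen, criterion_trace = trace,
      criterion_name = match.arg(criterion_name, c("bd", "sr", "lr")),
      k = k, column_names = colnames(x)[chosen]
    ),
    class = "fewt_selection"
  )
}
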