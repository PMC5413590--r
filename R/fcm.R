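#' Fuzzy c-means clustering
#'
#' Minimizes the fuzzified within-cluster sum of squared Euclidean distances
#' `A_m(U, V) = sum_j sum_i u_ij^m d^2(x_j, v_i)` subject to each object's
#' memberships summing to 1, by alternating the closed-form membership and
#' centroid updates. Memberships follow the inverse-distance rule
#' `u_ij = 1 / sum_r (d_ij / d_rj)^(2/(m-1))`; centroids are the
#' `u^m`-weighted means. When an object coincides with one or more centroids
#' the membership rule is undefined there, and membership 1 is split equally
#' among the coincident centroids.
#'
#' Initial centroids are `c` distinct data points drawn without replacement
#' under the given seed; the caller's RNG state is untouched.
#'
#' @param points Numeric matrix, one row per object (a vector is treated as
#'   one-dimensional data).
#' @param c Number of clusters, `1 < c < p`.
#' @param m Fuzzifier, `> 1` (default 2).
#' @param tol Convergence tolerance on the max absolute membership change
#'   (default `1e-6`).
#' @param max_iter Iteration cap (default 300).
#' @param seed Integer seed for the centroid initialization.
#' @param weights Optional non-negative per-object weights; the objective
#'   becomes `sum_j w_j sum_i u_ij^m d^2(x_j, v_i)`. Memberships are
#'   unaffected given the centroids; centroids become `w u^m`-weighted
#'   means. Default: uniform (the classic objective).
#' @return Object of class `"fewt_fcm"`: `memberships` (`c x p`),
#'   `centroids` (`c x d`), `objective_trace`, `fuzzifier`, `n_clusters`,
#'   `iterations`, `converged`.
#' @export
fcm_fit <- function(points, c, m = 2, tol = 1e-6, max_iter = 300L, seed = 1L,
                    weights = NULL) {
  x <- if (is.matrix(points)) points else matrix(as.numeric(points), ncol = 1L)
  storage.mode(x) <- "double"
  p <- nrow(x)
  if (!is.numeric(c) || length(c) != 1L || c <= 1 || c >= p) {
    stop("`c` must satisfy 1 < c < number of points", call. = FALSE)
  }
  c <- as.integer(c)
  if (m <= 1) stop("fuzzifier `m` must exceed 1", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  if (is.null(weights)) {
    w <- rep(1, p)
  } else {
    w <- as.numeric(weights)
    if (length(w) != p || any(!is.finite(w)) || any(w < 0) || sum(w) <= 0) {
      stop("`weights` must be non-negative with positive sum, one per point",
           call. = FALSE)
    }
  }

  # distinct rows so coincident points cannot collapse the initialization
  uniq <- unique(x)
  if (nrow(uniq) < c) {
    stop("fewer distinct points than clusters", call. = FALSE)
  }
  v <- with_seed(seed, uniq[sample.int(nrow(uniq), c), , drop = FALSE])

  expo <- 2 / (m - 1)
  u_prev <- NULL
  trace <- numeric(max_iter)
  converged <- FALSE
  iter <- 0L
  u <- NULL
  pow_m <- function(u) if (m == 2) u * u else u^m
  repeat {
    iter <- iter + 1L
    d2 <- sq_dist(v, x)                       # c x p squared distances
    u <- memberships_from_d2(d2, expo)
    um <- pow_m(u)
    umw <- um * rep(w, each = nrow(um))
    v <- (umw %*% x) / pmax(rowSums(umw), 1e-300)
    trace[iter] <- sum(umw * sq_dist(v, x))
    if (!is.null(u_prev) && max(abs(u - u_prev)) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    u_prev <- u
  }
  trace <- trace[seq_len(iter)]
  structure(
    list(
      memberships = u, centroids = v, objective_trace = trace,
      fuzzifier = m, n_clusters = c, iterations = iter, converged = converged
    ),
    class = "fewt_fcm"
  )
}

# c x p matrix of squared Euclidean distances between centroid rows and
# data rows.
sq_dist <- function(v, x) {
  d2 <- -2 * tcrossprod(v, x)
  d2 <- d2 + rowSums(v^2)                      # recycles down columns
  d2 <- d2 + rep(rowSums(x^2), each = nrow(v))
  d2[d2 < 0] <- 0
  d2
}

memberships_from_d2 <- function(d2, expo) {
  c_ <- nrow(d2); p <- ncol(d2)
  # u_ij proportional to d_ij^{-2/(m-1)} = (d2_ij)^{-1/(m-1)}
  w <- if (expo == 2) 1 / d2 else d2^(-expo / 2)
  zero <- d2 <= .Machine$double.eps^2
  hit <- colSums(zero) > 0L
  u <- w / rep(colSums(w), each = c_)
  if (any(hit)) {
    for (j in which(hit)) {
      z <- zero[, j]
      u[, j] <- 0
      u[z, j] <- 1 / sum(z)   # ties split equally among coincident centroids
    }
  }
  u
}

# FCM objective for explicit (U, V); used by tests and band refinement.
fcm_objective <- function(x, u, v, m = 2) {
  x <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
  sum(u^m * sq_dist(v, x))
}
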