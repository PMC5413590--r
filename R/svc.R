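# Gaussian-kernel least-squares support-vector classifier.
#
# The classification harness needs an RBF-kernel SVC with a regularization
# constant C and kernel width gamma. No SVM library is available in the
# target environment, so a least-squares SVM (Suykens form) is implemented
# here: equality-constrained ridge in the kernel feature space, solved as
# one linear system
#     [ 0   1' ] [ b ]   [ 0 ]
#     [ 1  K + I/C ] [ a ] = [ y ]
# with y in {-1, +1}. Deterministic, no tuning heuristics.

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * a %*% t(b)
  exp(-gamma * pmax(d2, 0))
}

#' Train a Gaussian-kernel least-squares SVC
#'
#' @param x Numeric matrix of training rows.
#' @param y Two-level class labels.
#' @param C Regularization constant (larger = less regularization).
#' @param gamma RBF kernel width parameter.
#' @return Object of class `"fewt_svc"`.
#' @export
svc_fit <- function(x, y, C = 1, gamma = 0.1) {
  x <- as.matrix(x)
  y <- as.character(y)
  cls <- sort(unique(y))
  if (length(cls) != 2L) stop("binary classifier: exactly 2 classes required", call. = FALSE)
  yy <- ifelse(y == cls[2L], 1, -1)
  n <- nrow(x)
  K <- rbf_kernel(x, x, gamma)
  A <- rbind(
    c(0, rep(1, n)),
    cbind(1, K + diag(n) / C)
  )
  sol <- tryCatch(
    solve(A, c(0, yy)),
    error = function(e) solve(A + diag(1e-10, n + 1L), c(0, yy))
  )
  structure(
    list(x = x, alpha = sol[-1L], b = sol[1L], gamma = gamma, classes = cls),
    class = "fewt_svc"
  )
}

#' Predict with a trained SVC
#'
#' @param object A `"fewt_svc"` model.
#' @param newdata Numeric matrix of rows to classify.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.fewt_svc <- function(object, newdata, ...) {
  K <- rbf_kernel(as.matrix(newdata), object$x, object$gamma)
  score <- as.numeric(K %*% object$alpha) + object$b
  ifelse(score >= 0, object$classes[2L], object$classes[1L])
}
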