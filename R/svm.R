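# Minimal C-SVM built on the package's SMO solver (no external SVM library
# is assumed). Kernels: RBF (default) and linear. Deterministic given inputs.

kernel_matrix <- function(X, Y = NULL, kernel = "rbf", gamma = 1) {
  X <- as.matrix(X)
  Y <- if (is.null(Y)) X else as.matrix(Y)
  if (kernel == "linear") return(X %*% t(Y))
  if (kernel != "rbf") stop("unknown kernel: ", kernel)
  xx <- rowSums(X^2); yy <- rowSums(Y^2)
  d2 <- outer(xx, yy, "+") - 2 * (X %*% t(Y))
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Fit a binary C-SVM
#'
#' @param X Numeric matrix (rows = examples).
#' @param y Labels in `{0, 1}` (or `{-1, 1}`).
#' @param C Soft-margin cost.
#' @param gamma RBF kernel width.
#' @param kernel `"rbf"` or `"linear"`.
#' @param eps SMO stopping tolerance.
#' @return An object of class `cj_svm`.
#' @export
svm_fit <- function(X, y, C = 1, gamma = 1, kernel = "rbf", eps = 1e-3) {
  X <- as.matrix(X)
  yy <- ifelse(y > 0, 1L, -1L)
  if (length(unique(yy)) < 2L) stop("both classes must be present")
  K <- kernel_matrix(X, kernel = kernel, gamma = gamma)
  sol <- .smo_solve(K, yy, C, eps, max_iter = 200L * nrow(X) + 10000L)
  sv <- which(sol$alpha > 1e-8)
  structure(list(X_sv = X[sv, , drop = FALSE],
                 coef = sol$alpha[sv] * yy[sv], b = sol$b,
                 kernel = kernel, gamma = gamma, C = C), class = "cj_svm")
}

#' Decision values and predictions for a fitted C-SVM
#' @param object A `cj_svm` fit.
#' @param newdata Numeric matrix.
#' @param ... Unused.
#' @return Integer vector of labels in `{0, 1}`.
#' @export
predict.cj_svm <- function(object, newdata, ...) {
  f <- svm_decision(object, newdata)
  as.integer(f > 0)
}

svm_decision <- function(fit, newdata) {
  K <- kernel_matrix(as.matrix(newdata), fit$X_sv,
                     kernel = fit$kernel, gamma = fit$gamma)
  drop(K %*% fit$coef) + fit$b
}
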