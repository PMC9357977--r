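#' Kernel specification
#'
#' The four supported kernels:
#' linear \eqn{x \cdot z}; polynomial \eqn{((x \cdot z) + 1)^d};
#' radial basis \eqn{\exp(-||x-z||^2 / (2\sigma^2))};
#' sigmoid \eqn{\tanh(k (x \cdot z) + \theta)}.
#'
#' @param kind one of `"linear"`, `"polynomial"`, `"rbf"`, `"sigmoid"`.
#' @param degree polynomial order d (default 3).
#' @param sigma rbf radius, must be > 0 (default 1).
#' @param k_scale,theta sigmoid scale and shift (defaults 1, 0).
#' @return a `kernel_spec` object.
#' @export
kernel_spec <- function(kind = c("linear", "polynomial", "rbf", "sigmoid"),
                        degree = 3L, sigma = 1, k_scale = 1, theta = 0) {
  kind <- match.arg(kind)
  if (kind == "rbf" && sigma <= 0) {
    stop_forgenet("sigma must be > 0", "forgenet_input_error")
  }
  if (kind == "polynomial" && degree < 1) {
    stop_forgenet("degree must be >= 1", "forgenet_input_error")
  }
  structure(list(kind = kind, degree = degree, sigma = sigma,
                 k_scale = k_scale, theta = theta),
            class = "kernel_spec")
}

#' Evaluate a kernel on two vectors
#' @param x,z numeric vectors of equal length.
#' @param spec a `kernel_spec`.
#' @return the scalar kernel value.
#' @export
kernel_eval <- function(x, z, spec) {
  if (length(x) != length(z)) {
    stop_forgenet("kernel arguments differ in length", "forgenet_input_error")
  }
  drop(kernel_matrix(matrix(x, 1), matrix(z, 1), spec))
}

#' Kernel (Gram) matrix between row sets
#' @param X,Z numeric matrices with equal column counts.
#' @param spec a `kernel_spec`.
#' @return `nrow(X)` x `nrow(Z)` kernel matrix.
#' @export
kernel_matrix <- function(X, Z = X, spec = kernel_spec("linear")) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (ncol(X) != ncol(Z)) {
    stop_forgenet("feature width mismatch", "forgenet_input_error")
  }
  G <- tcrossprod(X, Z)
  switch(spec$kind,
    linear = G,
    polynomial = (G + 1)^spec$degree,
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * G
      exp(-pmax(d2, 0) / (2 * spec$sigma^2))
    },
    sigmoid = tanh(spec$k_scale * G + spec$theta)
  )
}

#' Train a soft-margin kernel SVM by SMO
#'
#' Solves the dual problem
#' \deqn{\min_\alpha \tfrac12 \sum_{ij} \alpha_i \alpha_j y_i y_j K(x_i,x_j) - \sum_i \alpha_i}
#' subject to \eqn{\sum_i \alpha_i y_i = 0} and \eqn{0 \le \alpha_i \le C}
#' by sequential minimal optimization (pairwise updates preserve the
#' equality constraint exactly). The printed hard-margin dual is the
#' large-C limit. The bias is recovered as the mean over free support
#' vectors (0 < alpha < C) of \eqn{y_k - \sum_i \alpha_i y_i K(x_i,x_k)};
#' with no free support vector, the midpoint of the feasible interval.
#'
#' @param X training matrix (n x d).
#' @param y +1/-1 labels.
#' @param spec a `kernel_spec` (default linear).
#' @param C box constraint (default 1).
#' @param tol KKT violation tolerance: training stops when the maximal
#'   violating pair's gap falls below `tol` (default 1e-4).
#' @param max_iter pair-update cap before declaring non-convergence
#'   (default `max(1e5, 200 * n)`).
#' @return an `svm_model`: support vectors, their `alpha` and labels,
#'   bias `b`, `spec`, `C`, and the attained dual objective.
#' @export
train_svm <- function(X, y, spec = kernel_spec("linear"), C = 1,
                      tol = 1e-4, max_iter = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(unique(y)) < 2L) {
    stop_forgenet("both classes must be present", "forgenet_input_error")
  }
  max_iter <- max_iter %||% max(2e5, 500L * n)
  K <- kernel_matrix(X, X, spec)
  sol <- .svm_smo_cpp(K, y, C, tol, as.integer(max_iter))
  if (!sol$converged && sol$iterations > max_iter) {
    stop_forgenet(sprintf(
      "SMO did not converge within %d pair updates (n=%d, C=%g, kernel=%s, gap=%.3g)",
      max_iter, n, C, spec$kind, sol$gap), "forgenet_solver_error")
  }
  alpha <- as.numeric(sol$alpha)

  f_nob <- as.numeric(K %*% (alpha * y))
  free <- which(alpha > 1e-8 & alpha < C - 1e-8)
  if (length(free)) {
    b <- mean(y[free] - f_nob[free])
  } else {
    # feasible interval midpoint from bound examples
    lo_set <- c(which(alpha < 1e-8 & y == 1), which(alpha > C - 1e-8 & y == -1))
    hi_set <- c(which(alpha < 1e-8 & y == -1), which(alpha > C - 1e-8 & y == 1))
    lo <- if (length(lo_set)) max(y[lo_set] - f_nob[lo_set]) else -Inf
    hi <- if (length(hi_set)) min(y[hi_set] - f_nob[hi_set]) else Inf
    b <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2 else 0
  }

  ay <- alpha * y
  obj <- sum(alpha) - 0.5 * drop(crossprod(ay, K %*% ay))
  sv <- which(alpha > 1e-8)
  structure(list(SV = X[sv, , drop = FALSE], alpha = alpha[sv],
                 sv_labels = y[sv], b = b, spec = spec, C = C,
                 n_features = ncol(X), dual_objective = obj,
                 alpha_full = alpha, sum_alpha_y = sum(ay)),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("svm_model: %s kernel, C=%g, %d support vectors, b*=%.6g\n",
              x$spec$kind, x$C, length(x$alpha), x$b))
  invisible(x)
}

#' Predict with a trained SVM
#'
#' Decision value \eqn{f(x) = \sum_i \alpha_i^* y_i K(x_i, x) + b^*};
#' the label is its sign with sign(0) mapped to +1.
#'
#' @param object an `svm_model`.
#' @param newdata matrix with the training feature width.
#' @param ... unused.
#' @return list with `label` (+1/-1 vector) and `decision` (raw values,
#'   usable for ROC ranking).
#' @export
predict.svm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop_forgenet(sprintf("expected %d features, got %d",
                          object$n_features, ncol(newdata)),
                  "forgenet_input_error")
  }
  Kx <- kernel_matrix(newdata, object$SV, object$spec)
  dec <- as.numeric(Kx %*% (object$alpha * object$sv_labels)) + object$b
  list(label = ifelse(dec >= 0, 1, -1), decision = dec)
}

#' Export an SVM model as JSON
#' @param model an `svm_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_svm_model <- function(model, path) {
  jsonlite::write_json(
    list(kernel = unclass(model$spec), C = model$C, b = model$b,
         alpha_y = model$alpha * model$sv_labels,
         support_vectors = model$SV),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
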