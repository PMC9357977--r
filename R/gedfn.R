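#' Train the graph-embedded deep feed-forward network
#'
#' Architecture: input (d features) -> masked layer of d units, where
#' the d x d input weight matrix is Hadamard-masked by the feature-graph
#' adjacency so a unit only receives its graph neighbours -> two dense
#' hidden layers -> 2-unit softmax head. Hidden activations are ReLU;
#' the loss is (optionally class-weighted) cross-entropy minimised by
#' mini-batch Adam. Masked entries of the input weights are exactly zero
#' after every update.
#'
#' @param X numeric matrix (n x d) or `fused_features` object.
#' @param y +1/-1 labels (taken from `X$labels` if missing).
#' @param graph a `feature_graph` with `n_features == ncol(X)`.
#' @param epochs training epochs (default 50).
#' @param lr learning rate (default 1e-4).
#' @param seed integer seed for init and batch shuffling.
#' @param hidden widths of the two dense hidden layers (default c(64, 16)).
#' @param batch_size mini-batch size (default 32).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param class_weights optional c(inactive, active) loss weights;
#'   NULL = unweighted.
#' @return a `gedfn_model` with weights, config and the per-epoch loss
#'   trace.
#' @export
train_gedfn <- function(X, y = NULL, graph, epochs = 50L, lr = 1e-4,
                        seed = 1L, hidden = c(64L, 16L), batch_size = 32L,
                        optimizer = c("adam", "sgd"), class_weights = NULL) {
  optimizer <- match.arg(optimizer)
  if (inherits(X, "fused_features")) {
    y <- y %||% X$labels
    X <- X$matrix
  }
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (graph$n_features != d) {
    stop_forgenet(sprintf("graph has %d features but X has %d columns",
                          graph$n_features, d),
                  "forgenet_input_error")
  }
  if (is.null(y) || length(unique(y)) < 2L) {
    stop_forgenet("both classes must be present", "forgenet_input_error")
  }
  A <- graph_mask(graph)
  # one-hot targets, column 1 = inactive (-1), column 2 = active (+1)
  Tg <- cbind(as.numeric(y == -1), as.numeric(y == 1))
  wts <- if (is.null(class_weights)) c(1, 1) else class_weights
  wrow <- ifelse(y == 1, wts[2], wts[1])

  # init and shuffling use the R RNG; the compiled loop is deterministic
  pieces <- with_seed(seed, {
    init <- function(nin, nout) {
      matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
    }
    W0 <- list(W_in = init(d, d) * A, b_in = numeric(d),
               W1 = init(d, hidden[1]), b1 = numeric(hidden[1]),
               W2 = init(hidden[1], hidden[2]), b2 = numeric(hidden[2]),
               W_out = init(hidden[2], 2), b_out = numeric(2))
    perms <- t(vapply(seq_len(epochs), function(e) sample.int(n) - 1L,
                      integer(n)))
    list(W0 = W0, perms = perms)
  })
  fit <- .gedfn_train_cpp(X, Tg, A,
                          pieces$W0$W_in, pieces$W0$b_in,
                          pieces$W0$W1, pieces$W0$b1,
                          pieces$W0$W2, pieces$W0$b2,
                          pieces$W0$W_out, pieces$W0$b_out,
                          pieces$perms, wrow,
                          lr, as.integer(batch_size), optimizer == "adam")
  W <- list(W_in = fit$W_in, b_in = as.numeric(fit$b_in),
            W1 = fit$W1, b1 = as.numeric(fit$b1),
            W2 = fit$W2, b2 = as.numeric(fit$b2),
            W_out = fit$W_out, b_out = as.numeric(fit$b_out))
  structure(list(weights = W, hidden = hidden, n_features = d,
                 activation = "relu",
                 loss_trace = as.numeric(fit$loss_trace),
                 config = list(epochs = epochs, lr = lr, seed = seed,
                               batch_size = batch_size,
                               optimizer = optimizer,
                               class_weights = class_weights)),
            class = "gedfn_model")
}

#' @export
print.gedfn_model <- function(x, ...) {
  cat(sprintf("gedfn_model: %d -> %d(masked) -> %s -> 2, final loss %.4f\n",
              x$n_features, x$n_features,
              paste(x$hidden, collapse = " -> "),
              utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Class probabilities from a trained network (diagnostic head)
#' @param object a `gedfn_model`.
#' @param newdata matrix with `n_features` columns.
#' @param ... unused.
#' @return n x 2 matrix of softmax probabilities (inactive, active).
#' @export
predict.gedfn_model <- function(object, newdata, ...) {
  W <- object$weights
  X <- as.matrix(newdata)
  Z1 <- pmax(sweep(X %*% W$W_in, 2, W$b_in, "+"), 0)
  Z2 <- pmax(sweep(Z1 %*% W$W1, 2, W$b1, "+"), 0)
  Z3 <- pmax(sweep(Z2 %*% W$W2, 2, W$b2, "+"), 0)
  logits <- sweep(Z3 %*% W$W_out, 2, W$b_out, "+")
  shift <- logits - apply(logits, 1, max)
  P <- exp(shift) / rowSums(exp(shift))
  colnames(P) <- c("inactive", "active")
  P
}

#' Graph Connection Weights feature importance
#'
#' Scores feature i as the sum of the absolute masked input weights into
#' and out of its hidden unit plus the absolute weights from that unit
#' into the next hidden layer:
#' \deqn{c_i = \sum_a |W^{in}_{ia}| 1(A_{ia}=1) + \sum_b |W^{in}_{bi}| 1(A_{bi}=1) + \sum_c |W^{(1)}_{ic}|.}
#' The third sum is ungated by default; `gated = TRUE` gates it on the
#' feature's self-loop indicator (identically 1 after graph
#' finalization, so the two variants coincide on finalized graphs).
#'
#' @param model a `gedfn_model`.
#' @param graph the `feature_graph` the model was trained with.
#' @param gated gate the third term on diag(A) (default FALSE).
#' @return an `importance_scores` object: non-negative `score` vector
#'   and `ranking` (feature indices by descending score, ties by
#'   ascending index).
#' @export
gcw_scores <- function(model, graph, gated = FALSE) {
  if (graph$n_features != model$n_features) {
    stop_forgenet("graph/model feature count mismatch", "forgenet_input_error")
  }
  A <- graph_mask(graph)
  W_in <- model$weights$W_in
  W1 <- model$weights$W1
  third <- rowSums(abs(W1))
  if (gated) third <- third * as.numeric(diag(A) == 1)
  sc <- rowSums(abs(W_in) * A) + colSums(abs(W_in) * A) + third
  structure(list(score = as.numeric(sc),
                 ranking = order(-sc, seq_along(sc))),
            class = "importance_scores")
}

#' @export
print.importance_scores <- function(x, ...) {
  cat(sprintf("importance_scores over %d features; top 5: %s\n",
              length(x$score),
              paste(utils::head(x$ranking, 5), collapse = ", ")))
  invisible(x)
}

#' Select the top-k features by importance
#'
#' @param scores an `importance_scores` object (or bare numeric vector).
#' @param k number of features to keep.
#' @return integer vector of length `k`: feature indices in descending
#'   score order, ties broken by ascending index.
#' @export
select_top_k <- function(scores, k = 900L) {
  sc <- if (inherits(scores, "importance_scores")) scores$score else as.numeric(scores)
  if (k < 1L || k > length(sc)) {
    stop_forgenet(sprintf("k must be in [1, %d], got %s", length(sc), k),
                  "forgenet_input_error")
  }
  order(-sc, seq_along(sc))[seq_len(k)]
}

#' Export importance scores as TSV
#' @param scores an `importance_scores` object.
#' @param path output path.
#' @param feature_names optional column names for the features.
#' @return `path`, invisibly.
#' @export
write_importance <- function(scores, path, feature_names = NULL) {
  nms <- feature_names %||% sprintf("f%06d", seq_along(scores$score))
  rank <- integer(length(scores$score))
  rank[scores$ranking] <- seq_along(scores$ranking)
  utils::write.table(
    data.frame(feature_name = nms, score = scores$score, rank = rank),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
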