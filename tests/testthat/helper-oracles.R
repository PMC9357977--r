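# Independent brute-force oracles and small generators used across the
# suite. Each oracle is written directly from the defining formula, not
# from the package implementation it checks.

# GCW importance by triple loop: in-edges + out-edges of the masked
# input weights, plus (ungated) the outgoing first-hidden-layer weights.
gcw_brute <- function(W_in, W1, A) {
  n <- nrow(W_in)
  c_out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (a in seq_len(n)) if (A[i, a] == 1) s <- s + abs(W_in[i, a])
    for (b in seq_len(n)) if (A[b, i] == 1) s <- s + abs(W_in[b, i])
    for (cc in seq_len(ncol(W1))) s <- s + abs(W1[i, cc])
    c_out[i] <- s
  }
  c_out
}

# A random untrained network/graph pair over d features.
random_gedfn_model <- function(d, h1 = 4L) {
  n_edges <- sample(0:(d * 2), 1)
  edges <- if (n_edges > 0) {
    cbind(sample.int(d, n_edges, replace = TRUE),
          sample.int(d, n_edges, replace = TRUE))
  } else {
    matrix(integer(0), 0, 2)
  }
  graph <- aggregate_graphs(list(edges), d)
  A <- as.matrix(graph$adjacency) * 1
  W_in <- matrix(rnorm(d * d), d, d) * A
  W1 <- matrix(rnorm(d * h1), d, h1)
  model <- structure(list(
    weights = list(W_in = W_in, b_in = numeric(d), W1 = W1,
                   b1 = numeric(h1),
                   W2 = matrix(rnorm(h1 * 2), h1, 2), b2 = numeric(2),
                   W_out = matrix(rnorm(4), 2, 2), b_out = numeric(2)),
    hidden = c(h1, 2L), n_features = d, activation = "relu",
    loss_trace = numeric(0), config = list()), class = "gedfn_model")
  list(model = model, graph = graph, A = A)
}

# Recursive descent over a node table: collects (parent split feature,
# child split feature) pairs along every root-to-leaf path.
tree_edges_recursive <- function(tree) {
  sv <- rep(NA_integer_, max(tree$nodeID) + 1L)
  sv[tree$nodeID + 1L] <- tree$splitvarID
  term <- rep(TRUE, max(tree$nodeID) + 1L)
  term[tree$nodeID + 1L] <- tree$terminal
  kids <- matrix(NA_integer_, max(tree$nodeID) + 1L, 2)
  kids[tree$nodeID + 1L, ] <- cbind(tree$leftChild, tree$rightChild)
  acc <- list()
  walk <- function(node) {
    if (term[node + 1L]) return(invisible())
    for (ch in kids[node + 1L, ]) {
      if (!is.na(ch)) {
        if (!term[ch + 1L]) {
          acc[[length(acc) + 1L]] <<- c(sv[node + 1L] + 1L, sv[ch + 1L] + 1L)
        }
        walk(ch)
      }
    }
  }
  walk(tree$nodeID[1])
  if (length(acc)) unique(do.call(rbind, acc)) else matrix(integer(0), 0, 2)
}

# A random binary tree in node-table form with `n_nodes` nodes.
random_tree_table <- function(n_nodes, n_features = 6L) {
  stopifnot(n_nodes %% 2 == 1)
  nodes <- data.frame(nodeID = 0L, leftChild = NA_integer_,
                      rightChild = NA_integer_,
                      splitvarID = NA_integer_, terminal = TRUE)
  while (nrow(nodes) < n_nodes) {
    leaf_rows <- which(nodes$terminal)
    r <- sample(leaf_rows, 1)
    id_l <- nrow(nodes); id_r <- nrow(nodes) + 1L
    nodes$terminal[r] <- FALSE
    nodes$splitvarID[r] <- sample.int(n_features, 1) - 1L
    nodes$leftChild[r] <- id_l
    nodes$rightChild[r] <- id_r
    nodes <- rbind(nodes,
                   data.frame(nodeID = c(id_l, id_r),
                              leftChild = NA_integer_,
                              rightChild = NA_integer_,
                              splitvarID = NA_integer_, terminal = TRUE))
  }
  nodes
}

# Dense boolean-matrix union of edge sets, symmetrized with unit diag.
union_brute <- function(graphs, n_features) {
  A <- matrix(FALSE, n_features, n_features)
  for (g in graphs) {
    for (r in seq_len(nrow(g))) A[g[r, 1], g[r, 2]] <- TRUE
  }
  A <- A | t(A)
  diag(A) <- TRUE
  A
}

# Exhaustive dual solve for the soft-margin SVM: every assignment of
# each alpha_i to {0, C, free} defines a KKT subsystem; the optimum of
# the concave dual is the best feasible stationary candidate.
svm_dual_brute <- function(K, y, C) {
  n <- length(y)
  Q <- (y %*% t(y)) * K
  obj <- function(a) sum(a) - 0.5 * drop(t(a) %*% Q %*% a)
  best <- -Inf
  states <- expand.grid(rep(list(0:2), n))  # 0 -> 0, 1 -> C, 2 -> free
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    a <- ifelse(st == 1L, C, 0)
    free <- which(st == 2L)
    if (length(free)) {
      bound <- which(st != 2L)
      M <- rbind(cbind(Q[free, free, drop = FALSE], y[free]),
                 c(y[free], 0))
      qb <- if (length(bound)) {
        as.numeric(Q[free, bound, drop = FALSE] %*% a[bound])
      } else {
        numeric(length(free))
      }
      rhs <- c(1 - qb, -sum(a[bound] * y[bound]))
      sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      af <- sol[seq_along(free)]
      if (any(af < -1e-9 | af > C + 1e-9)) next
      a[free] <- pmin(pmax(af, 0), C)
    }
    if (abs(sum(a * y)) > 1e-8) next
    best <- max(best, obj(a))
  }
  best
}

# Linearly separable two-class toy in 2D with a comfortable margin.
random_separable_toy <- function(n = 6L) {
  repeat {
    n_pos <- sample(1:(n - 1), 1)
    X <- rbind(matrix(rnorm(n_pos * 2, mean = 2.5, sd = 0.5), ncol = 2),
               matrix(rnorm((n - n_pos) * 2, mean = -2.5, sd = 0.5), ncol = 2))
    y <- c(rep(1, n_pos), rep(-1, n - n_pos))
    if (min(X[y == 1, 1]) - max(X[y == -1, 1]) > 1) return(list(X = X, y = y))
  }
}

# Small planted dataset used by fast pipeline tests.
small_planted <- function(seed = 1L, m = 20L, d = 40L) {
  generate_planted(planted_spec(m = m, d = d, n_informative = 6L,
                                n_real_cols = 8L, seed = seed))
}

# Fast pipeline config for unit tests (full defaults are exercised in
# the acceptance suite).
small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(trees = 60L, epochs = 10L, k_selected = 10L, cv_folds = 4L,
         hidden = c(16L, 8L), seed = seed),
    list(...))
  do.call(pipeline_config, args)
}
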