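#' Fit a random forest on a fused feature matrix
#'
#' Classification forest (Gini impurity, bootstrap resampling, sqrt
#' feature subsampling) whose trees are later converted into a feature
#' graph. Reproducible for a given seed; single-threaded so that tree
#' structures are identical across runs.
#'
#' @param X numeric matrix or `fused_features` object.
#' @param y +1/-1 label vector (taken from `X$labels` if missing).
#' @param p number of trees (default 1000).
#' @param seed integer seed.
#' @param mtry features tried per split; default `floor(sqrt(ncol(X)))`.
#' @return a `forest_model` wrapping the fitted ranger object.
#' @export
fit_forest <- function(X, y = NULL, p = 1000L, seed = 1L, mtry = NULL) {
  if (inherits(X, "fused_features")) {
    y <- y %||% X$labels
    X <- X$matrix
  }
  X <- as.matrix(X)
  if (is.null(y)) stop_forgenet("labels required", "forgenet_input_error")
  if (nrow(X) < 2L) stop_forgenet("need at least 2 rows", "forgenet_input_error")
  if (length(unique(y)) < 2L) {
    stop_forgenet("both classes must be present to fit the forest",
                  "forgenet_input_error")
  }
  if (p < 1L) stop_forgenet("p must be >= 1", "forgenet_input_error")
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(X))))
  colnames(X) <- sprintf("f%06d", seq_len(ncol(X)))
  fit <- ranger::ranger(
    x = X, y = factor(y, levels = c(-1, 1)),
    num.trees = p, mtry = mtry, splitrule = "gini",
    replace = TRUE, seed = as.integer(seed), num.threads = 1L
  )
  structure(list(fit = fit, p = as.integer(p), n_features = ncol(X),
                 seed = as.integer(seed)),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("forest_model: %d trees over %d features (seed %d)\n",
              x$p, x$n_features, x$seed))
  invisible(x)
}

# Structure of tree t as a node table (nodeID, leftChild, rightChild,
# splitvarID 0-based, terminal), the representation tree_to_graph consumes.
tree_table <- function(forest, t) {
  ti <- ranger::treeInfo(forest$fit, t)
  data.frame(nodeID = ti$nodeID, leftChild = ti$leftChild,
             rightChild = ti$rightChild, splitvarID = ti$splitvarID,
             terminal = ti$terminal)
}

#' Convert one decision tree into a directed feature edge set
#'
#' Walking every root-to-leaf path, consecutive split features become
#' directed edges (parent split feature -> child split feature); leaves
#' contribute no vertices and duplicate edges collapse. A stump yields
#' an empty edge set.
#'
#' @param tree a node table: columns `nodeID`, `leftChild`, `rightChild`,
#'   `splitvarID` (0-based feature index, NA at leaves), `terminal`.
#' @return two-column integer matrix of directed edges (1-based feature
#'   indices), zero rows when no internal parent-child pair exists.
#' @export
tree_to_graph <- function(tree) {
  stopifnot(all(c("nodeID", "leftChild", "rightChild", "splitvarID",
                  "terminal") %in% names(tree)))
  splitvar <- rep(NA_integer_, max(tree$nodeID) + 1L)
  splitvar[tree$nodeID + 1L] <- as.integer(tree$splitvarID)
  internal <- tree[!tree$terminal, , drop = FALSE]
  edges <- matrix(integer(0), 0, 2)
  for (i in seq_len(nrow(internal))) {
    pf <- splitvar[internal$nodeID[i] + 1L]
    for (child in c(internal$leftChild[i], internal$rightChild[i])) {
      if (!is.na(child)) {
        cf <- splitvar[child + 1L]
        if (!is.na(cf)) edges <- rbind(edges, c(pf + 1L, cf + 1L))
      }
    }
  }
  unique(edges)
}

#' Edge sets of every tree in a forest
#'
#' Reads the fitted trees' split structure directly (child node ids and
#' split-variable ids) and applies the same parent-child rule as
#' [tree_to_graph()]; the two paths are cross-checked in the test
#' suite.
#'
#' @param forest a `forest_model`.
#' @return list of directed edge matrices, one per tree.
#' @export
forest_edge_sets <- function(forest) {
  fo <- forest$fit$forest
  lapply(seq_len(forest$p), function(t) {
    left <- fo$child.nodeIDs[[t]][[1]]
    right <- fo$child.nodeIDs[[t]][[2]]
    sv <- fo$split.varIDs[[t]]
    internal <- which(left > 0 | right > 0)  # terminal nodes have 0/0 children
    pf <- rep(sv[internal], 2L)
    child <- c(left[internal], right[internal]) + 1L
    keep <- child %in% internal  # child must itself be a split node
    unique(cbind(pf[keep] + 1L, sv[child[keep]] + 1L))
  })
}

#' Aggregate per-tree edge sets into one feature graph
#'
#' Takes the set union of all directed edges, then finalizes the mask:
#' the adjacency is symmetrized (A | t(A)) and given a unit diagonal so
#' that every feature reaches its own hidden unit.
#'
#' @param graphs list of two-column edge matrices (1-based indices).
#' @param n_features number of features (graph vertex count).
#' @return a `feature_graph`: sparse logical adjacency + `n_features`.
#' @export
aggregate_graphs <- function(graphs, n_features) {
  all_edges <- do.call(rbind, c(list(matrix(integer(0), 0, 2)), graphs))
  if (nrow(all_edges) && max(all_edges) > n_features) {
    stop_forgenet("edge index exceeds n_features", "forgenet_input_error")
  }
  i <- c(all_edges[, 1], all_edges[, 2], seq_len(n_features))
  j <- c(all_edges[, 2], all_edges[, 1], seq_len(n_features))
  A <- Matrix::sparseMatrix(i = i, j = j, x = TRUE,
                            dims = c(n_features, n_features), use.last.ij = TRUE)
  A <- as(A, "lMatrix")
  structure(list(adjacency = A, n_features = as.integer(n_features)),
            class = "feature_graph")
}

#' Build the aggregated feature graph of a fitted forest
#'
#' Equivalent to `aggregate_graphs(forest_edge_sets(forest), ...)` but
#' skips per-tree deduplication (the sparse union collapses duplicates
#' anyway), which matters at 1000 trees.
#'
#' @param forest a `forest_model`.
#' @return a `feature_graph` over the forest's feature space.
#' @export
forest_graph <- function(forest) {
  fo <- forest$fit$forest
  us <- vector("list", forest$p)
  vs <- vector("list", forest$p)
  for (t in seq_len(forest$p)) {
    left <- fo$child.nodeIDs[[t]][[1]]
    right <- fo$child.nodeIDs[[t]][[2]]
    sv <- fo$split.varIDs[[t]]
    internal <- which(left > 0 | right > 0)
    pf <- rep(sv[internal], 2L)
    child <- c(left[internal], right[internal]) + 1L
    keep <- child %in% internal
    us[[t]] <- pf[keep] + 1L
    vs[[t]] <- sv[child[keep]] + 1L
  }
  aggregate_graphs(list(cbind(unlist(us), unlist(vs))), forest$n_features)
}

#' @export
print.feature_graph <- function(x, ...) {
  nnz <- Matrix::nnzero(x$adjacency)
  cat(sprintf("feature_graph: %d features, %d adjacency entries (%d off-diagonal edges)\n",
              x$n_features, nnz, (nnz - x$n_features) / 2))
  invisible(x)
}

# Dense 0/1 mask used by the network layer.
graph_mask <- function(graph) {
  M <- as.matrix(graph$adjacency)
  storage.mode(M) <- "double"
  M
}

#' Write a feature graph as an edge list
#'
#' One `u<TAB>v` line per strict-upper-triangle edge, 0-based indices,
#' preceded by a JSON header line (prefixed `#`) carrying `n_features`
#' and any metadata supplied.
#'
#' @param graph a `feature_graph`.
#' @param path output path.
#' @param meta named list merged into the header.
#' @return `path`, invisibly.
#' @export
write_feature_graph <- function(graph, path, meta = list()) {
  hdr <- jsonlite::toJSON(c(list(n_features = graph$n_features), meta),
                          auto_unbox = TRUE)
  S <- methods::as(Matrix::triu(graph$adjacency, k = 1), "TsparseMatrix")
  lines <- c(paste0("#", hdr),
             if (length(S@i)) sprintf("%d\t%d", S@i, S@j))
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature graph written by [write_feature_graph()]
#' @param path edge-list path.
#' @return a `feature_graph`.
#' @export
read_feature_graph <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  edges <- if (length(lines) > 1) {
    do.call(rbind, lapply(strsplit(lines[-1], "\t"),
                          function(p) as.integer(p) + 1L))
  } else {
    matrix(integer(0), 0, 2)
  }
  aggregate_graphs(list(edges), hdr$n_features)
}
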