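identity_graph <- function(d) aggregate_graphs(list(matrix(integer(0), 0, 2)), d)

test_that("training loss decreases on a separable identity task", {
  set.seed(3)
  X <- diag(8)[rep(1:8, 12), ]
  y <- ifelse(rep(1:8, 12) <= 4, 1L, -1L)
  net <- train_gedfn(X, y, identity_graph(8L), epochs = 5, lr = 0.05,
                     seed = 1, hidden = c(8L, 4L), batch_size = 16L)
  expect_length(net$loss_trace, 5L)
  expect_true(all(diff(net$loss_trace) < 0))
})

test_that("a richer mask reaches at most the restricted mask's loss", {
  set.seed(4)
  pl <- small_planted(seed = 5)
  d <- ncol(pl$data$matrix)
  full_edges <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
  all_ones <- aggregate_graphs(list(unname(full_edges)), d)
  losses <- vapply(1:3, function(s) {
    lid <- train_gedfn(pl$data, graph = identity_graph(d), epochs = 15,
                       lr = 1e-3, seed = s, hidden = c(16L, 8L))
    lfull <- train_gedfn(pl$data, graph = all_ones, epochs = 15,
                         lr = 1e-3, seed = s, hidden = c(16L, 8L))
    tail(lfull$loss_trace, 1) - tail(lid$loss_trace, 1)
  }, numeric(1))
  expect_lte(median(losses), 0)
})

test_that("masked entries stay exactly zero through training", {
  pl <- small_planted(seed = 6)
  fo <- fit_forest(pl$data, p = 30, seed = 1)
  g <- forest_graph(fo)
  net <- train_gedfn(pl$data, graph = g, epochs = 8, lr = 1e-3, seed = 2,
                     hidden = c(16L, 8L))
  A <- as.matrix(g$adjacency) * 1
  expect_identical(unname(net$weights$W_in * (1 - A)),
                   matrix(0, nrow(A), ncol(A)))
  # and the unmasked entries did move away from zero
  expect_gt(sum(net$weights$W_in != 0), 0)
})

test_that("softmax head yields probabilities summing to one", {
  pl <- small_planted(seed = 7)
  g <- identity_graph(ncol(pl$data$matrix))
  net <- train_gedfn(pl$data, graph = g, epochs = 3, seed = 1,
                     hidden = c(8L, 4L))
  P <- predict(net, pl$data$matrix)
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
})

test_that("GCW equals the brute-force summation on random models", {
  set.seed(9)
  for (rep in 1:25) {
    rm <- random_gedfn_model(sample(2:8, 1))
    got <- gcw_scores(rm$model, rm$graph)$score
    expect_lt(max(abs(got - gcw_brute(rm$model$weights$W_in,
                                      rm$model$weights$W1, rm$A))), 1e-10)
  }
})

test_that("GCW is non-negative, zero for zero weights, and 1-homogeneous", {
  set.seed(10)
  rm <- random_gedfn_model(6L)
  sc <- gcw_scores(rm$model, rm$graph)
  expect_true(all(sc$score >= 0))
  doubled <- rm$model
  doubled$weights$W_in <- 2 * doubled$weights$W_in
  doubled$weights$W1 <- 2 * doubled$weights$W1
  expect_equal(gcw_scores(doubled, rm$graph)$score, 2 * sc$score)
  zeroed <- rm$model
  zeroed$weights$W_in[] <- 0; zeroed$weights$W1[] <- 0
  expect_identical(gcw_scores(zeroed, rm$graph)$score, rep(0, 6))
  # gated variant coincides on finalized graphs (all self-loops present)
  expect_equal(gcw_scores(rm$model, rm$graph, gated = TRUE)$score, sc$score)
})

test_that("top-k selection obeys descending score with index tie-break", {
  expect_identical(select_top_k(c(3, 1, 2), 2), c(1L, 3L))
  expect_identical(select_top_k(rep(1, 5), 3), 1:3)
  set.seed(12)
  sc <- sample(rep(runif(20), length.out = 40))
  want <- order(-sc, seq_along(sc))[1:10]
  expect_identical(select_top_k(sc, 10), want)
  # idempotence: re-selecting k from the already-selected k is the identity
  sel <- select_top_k(sc, 10)
  resel <- sel[select_top_k(sc[sel], 10)]
  expect_identical(resel, sel)
  expect_error(select_top_k(sc, 0), class = "forgenet_input_error")
  expect_error(select_top_k(sc, 41), class = "forgenet_input_error")
})

test_that("dimension mismatches and single-class labels are rejected", {
  pl <- small_planted(seed = 13)
  g <- identity_graph(5L)
  expect_error(train_gedfn(pl$data, graph = g),
               class = "forgenet_input_error")
  X <- matrix(rnorm(20), 5, 4)
  expect_error(train_gedfn(X, rep(1L, 5), identity_graph(4L)),
               class = "forgenet_input_error")
})

test_that("importance TSV export carries scores and ranks", {
  set.seed(14)
  rm <- random_gedfn_model(5L)
  sc <- gcw_scores(rm$model, rm$graph)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_importance(sc, path, feature_names = letters[1:5])
  df <- read.delim(path)
  expect_identical(names(df), c("feature_name", "score", "rank"))
  expect_identical(df$feature_name[df$rank == 1], letters[sc$ranking[1]])
})
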