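test_that("kernel formulas match their closed forms", {
  expect_identical(kernel_eval(c(1, 0), c(0, 1), kernel_spec("linear")), 0)
  expect_identical(kernel_eval(c(1, 1), c(1, 0), kernel_spec("polynomial", degree = 2)), 4)
  expect_identical(kernel_eval(c(2, 3), c(2, 3), kernel_spec("rbf")), 1)
  x <- c(0.3, -1); z <- c(2, 0.5)
  expect_equal(kernel_eval(x, z, kernel_spec("rbf", sigma = 0.7)),
               exp(-sum((x - z)^2) / (2 * 0.7^2)))
  expect_equal(kernel_eval(x, z, kernel_spec("sigmoid", k_scale = 0.4, theta = 0.1)),
               tanh(0.4 * sum(x * z) + 0.1))
  expect_error(kernel_eval(1:3, 1:2, kernel_spec("linear")),
               class = "forgenet_input_error")
  expect_error(kernel_spec("rbf", sigma = 0), class = "forgenet_input_error")
})

test_that("Gram matrices are symmetric and PSD for linear/rbf", {
  set.seed(21)
  X <- matrix(rnorm(40), 8, 5)
  for (spec in list(kernel_spec("linear"), kernel_spec("rbf", sigma = 1.3))) {
    K <- kernel_matrix(X, X, spec)
    expect_equal(K, t(K))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("two symmetric points solve in closed form", {
  m <- train_svm(rbind(c(1, 0), c(-1, 0)), c(1, -1),
                 kernel_spec("linear"), C = 1e3)
  expect_equal(sort(m$alpha), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(m$b, 0, tolerance = 1e-6)
  pr <- predict(m, rbind(c(0.3, 7), c(-0.2, -5)))
  expect_identical(pr$label, c(1, -1))
  expect_equal(pr$decision, c(0.3, -0.2), tolerance = 1e-6)
})

test_that("rbf kernel separates XOR", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(1, 1, -1, -1)
  m <- train_svm(X, y, kernel_spec("rbf", sigma = 1), C = 1e3)
  expect_identical(predict(m, X)$label, y)
})

test_that("dual objective matches exhaustive enumeration on separable toys", {
  set.seed(22)
  for (rep in 1:20) {
    toy <- random_separable_toy(sample(3:6, 1))
    spec <- kernel_spec("linear")
    C <- 100
    m <- train_svm(toy$X, toy$y, spec, C = C, tol = 1e-6)
    expect_lte(abs(m$sum_alpha_y), 1e-6)
    K <- kernel_matrix(toy$X, toy$X, spec)
    expect_equal(m$dual_objective, svm_dual_brute(K, toy$y, C),
                 tolerance = 1e-4)
  }
})

test_that("solution satisfies the margin and box conditions", {
  set.seed(23)
  toy <- random_separable_toy(6)
  C <- 50
  m <- train_svm(toy$X, toy$y, kernel_spec("linear"), C = C, tol = 1e-6)
  expect_true(all(m$alpha > 0 & m$alpha <= C + 1e-9))
  # free support vectors sit on the margin
  free <- m$alpha > 1e-6 & m$alpha < C - 1e-6
  if (any(free)) {
    dec <- predict(m, m$SV[free, , drop = FALSE])$decision
    expect_true(all(abs(m$sv_labels[free] * dec - 1) < 1e-3))
  }
  # separable training data are fit exactly at large C
  expect_identical(predict(m, toy$X)$label, toy$y)
})

test_that("agrees with an independent SVM implementation on a toy", {
  skip_if_not_installed("e1071")
  set.seed(24)
  toy <- random_separable_toy(6)
  m <- train_svm(toy$X, toy$y, kernel_spec("linear"), C = 10, tol = 1e-6)
  ref <- e1071::svm(toy$X, factor(toy$y), kernel = "linear", cost = 10,
                    scale = FALSE)
  dec_ref <- attr(predict(ref, toy$X, decision.values = TRUE),
                  "decision.values")
  flip <- sign(cor(as.numeric(dec_ref), predict(m, toy$X)$decision))
  expect_equal(flip * as.numeric(dec_ref), predict(m, toy$X)$decision,
               tolerance = 1e-3)
})

test_that("consistent column permutation leaves predictions unchanged", {
  set.seed(25)
  X <- matrix(rnorm(60), 12, 5)
  y <- rep(c(1, -1), 6)
  Xnew <- matrix(rnorm(20), 4, 5)
  perm <- c(4, 2, 5, 1, 3)
  for (spec in list(kernel_spec("linear"), kernel_spec("rbf"),
                    kernel_spec("polynomial", degree = 2))) {
    m1 <- train_svm(X, y, spec, C = 1, tol = 1e-6)
    m2 <- train_svm(X[, perm], y, spec, C = 1, tol = 1e-6)
    expect_equal(predict(m1, Xnew)$decision, predict(m2, Xnew[, perm])$decision,
                 tolerance = 1e-6)
  }
})

test_that("sign(0) maps to the positive class and width is checked", {
  m <- train_svm(rbind(c(1, 0), c(-1, 0)), c(1, -1), C = 1e3)
  expect_identical(predict(m, rbind(c(0, 5)))$label, 1)
  expect_error(predict(m, matrix(0, 1, 3)), class = "forgenet_input_error")
  expect_error(train_svm(rbind(1:2, 3:4), c(1, 1)),
               class = "forgenet_input_error")
})

test_that("model JSON export is readable and complete", {
  m <- train_svm(rbind(c(1, 0), c(-1, 0)), c(1, -1), C = 1e3)
  path <- withr::local_tempfile(fileext = ".json")
  write_svm_model(m, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(j$kernel$kind, "linear")
  expect_equal(j$b, 0, tolerance = 1e-6)
  expect_equal(sort(unlist(j$alpha_y)), c(-0.5, 0.5), tolerance = 1e-6)
})
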