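# ML regressors: SVR, KRR, RF, Adaboost.R2 and grid search.

ml_sim <- function(n = 60L, p = 30L, seed = 1L, noise = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 2L, 0.35), n, p,
              dimnames = list(sprintf("I%03d", 1:n), sprintf("M%03d", 1:p)))
  y <- drop(X[, 1:5] %*% c(1, -0.8, 0.5, 0.4, -0.6)) + rnorm(n, 0, noise)
  list(X = X, y = y)
}

test_that("an epsilon tube wider than the response flattens the SVR", {
  sim <- ml_sim(seed = 2)
  eps <- diff(range(sim$y)) * 1.1
  fit <- fit_svr(sim$X, sim$y, svr_params(C = 7, gamma = 1e-4, epsilon = eps))
  pred <- predict(fit, sim$X)
  expect_true(all(abs(pred - sim$y) <= eps + 1e-6))
  expect_lt(sd(pred), 1e-6)
})

test_that("the SVR dual objective matches an interior-point QP solution", {
  skip_if_not_installed("kernlab")
  sim <- ml_sim(n = 10L, p = 6L, seed = 3)
  p <- svr_params(kernel = "rbf", C = 2, gamma = 0.05, epsilon = 0.1)
  fit <- fit_svr(sim$X, sim$y, p)
  K <- gsbench:::kernel_matrix(sim$X, sim$X, "rbf", p$gamma)
  # dual objective at the libsvm solution
  gam <- numeric(10L)
  gam[fit$svm$index] <- fit$svm$coefs
  obj_libsvm <- sum(sim$y * gam) - 0.5 * drop(t(gam) %*% K %*% gam) -
    p$epsilon * sum(abs(gam))
  # independent QP: variables (alpha, alpha*), equality sum(alpha - alpha*) = 0
  H <- rbind(cbind(K, -K), cbind(-K, K))
  cc <- c(p$epsilon - sim$y, p$epsilon + sim$y)
  A <- matrix(c(rep(1, 10), rep(-1, 10)), 1)
  qp <- kernlab::ipop(c = cc, H = H + diag(1e-10, 20), A = A, b = 0,
                      l = rep(0, 20), u = rep(p$C, 20), r = 0, sigf = 9)
  x <- kernlab::primal(qp)
  gam_qp <- x[1:10] - x[11:20]
  obj_qp <- sum(sim$y * gam_qp) - 0.5 * drop(t(gam_qp) %*% K %*% gam_qp) -
    p$epsilon * sum(abs(gam_qp))
  expect_equal(obj_libsvm, obj_qp, tolerance = 1e-4)
})

test_that("KRR interpolates as lambda approaches zero", {
  sim <- ml_sim(n = 30L, seed = 4)
  fit <- fit_krr(sim$X, sim$y, krr_params(kernel = "rbf", lam = 1e-10,
                                          gamma = 0.01))
  expect_lt(max(abs(predict(fit, sim$X) - sim$y)), 1e-6)
})

test_that("linear-kernel KRR coincides with primal ridge regression", {
  set.seed(5)
  X <- matrix(rnorm(100), 20, 5,
              dimnames = list(sprintf("I%02d", 1:20), sprintf("M%02d", 1:5)))
  y <- rnorm(20)
  lam <- 0.7
  fit <- fit_krr(X, y, krr_params(kernel = "linear", lam = lam, gamma = 1))
  beta_ridge <- solve(crossprod(X) + diag(lam, 5), crossprod(X, y))
  expect_lt(max(abs(predict(fit, X) - drop(X %*% beta_ridge))), 1e-6)
  # dual exactness: ||(K + lam I) a - y|| tiny
  K <- tcrossprod(X)
  expect_lt(max(abs((K + diag(lam, 20)) %*% fit$alpha - y)), 1e-8)
})

test_that("KRR rejects a singular system", {
  X <- matrix(c(1, 1, 0, 1, 1, 0), 3, 2,
              dimnames = list(c("a", "b", "c"), c("m1", "m2")))
  expect_error(fit_krr(X, c(1, 2, 3), krr_params(kernel = "linear", lam = 0,
                                                 gamma = 1)),
               "singular")
})

test_that("default ML parameters are the tuned optima", {
  expect_equal(svr_params()[c("kernel", "C", "gamma")],
               list(kernel = "rbf", C = 7, gamma = 1e-4))
  expect_equal(krr_params()[c("kernel", "lam", "gamma")],
               list(kernel = "rbf", lam = 0.1, gamma = 1e-4))
  rf <- rf_params()
  expect_equal(rf$n_estimators, 250L)
  expect_true(is.infinite(rf$max_depth))
  expect_equal(adaboost_params()$n_estimators, 50L)
})

test_that("random forest predicts constants for constant responses", {
  sim <- ml_sim(n = 30L, seed = 6)
  fit <- fit_rf(sim$X, rep(3.5, 30), rf_params(n_estimators = 20L, seed = 2L))
  expect_equal(predict(fit, sim$X), rep(3.5, 30))
})

test_that("a single depth-1 tree finds the variance-minimizing split", {
  set.seed(7)
  x <- matrix(sort(runif(40, 0, 10)), ncol = 1, dimnames = list(NULL, "x"))
  y <- ifelse(x[, 1] < 6.2, 1, 5) + rnorm(40, 0, 0.1)
  fit <- fit_rf(x, y, rf_params(n_estimators = 1L, max_depth = 1L,
                                replace = FALSE, sample_fraction = 1,
                                seed = 3L))
  split <- ranger::treeInfo(fit$forest, 1)$splitval[1]
  # exhaustive search over midpoints
  cand <- (head(sort(x[, 1]), -1) + tail(sort(x[, 1]), -1)) / 2
  sse <- vapply(cand, function(s) {
    l <- y[x[, 1] <= s]; r <- y[x[, 1] > s]
    sum((l - mean(l))^2) + sum((r - mean(r))^2)
  }, numeric(1))
  best <- cand[which.min(sse)]
  expect_equal(split, best, tolerance = 1e-8)
})

test_that("forest prediction is exactly the mean of its trees", {
  sim <- ml_sim(n = 40L, seed = 8)
  fit <- fit_rf(sim$X, sim$y, rf_params(n_estimators = 15L, seed = 4L))
  all_trees <- predict(fit$forest, data = as.data.frame(sim$X),
                       predict.all = TRUE, num.threads = 1L)$predictions
  expect_equal(predict(fit, sim$X), rowMeans(all_trees), tolerance = 1e-12)
})

test_that("the Adaboost.R2 weight update matches hand arithmetic", {
  upd <- gsbench:::adaboost_update_weights(rep(1 / 3, 3), c(0, 0.5, 1))
  expect_equal(upd$Lbar, 0.5)
  expect_equal(upd$beta, 1)        # Lbar / (1 - Lbar)
  expect_equal(upd$D, rep(1 / 3, 3))
  expect_equal(sum(upd$D), 1)
  # a non-degenerate case, fully by hand
  D <- c(0.2, 0.3, 0.5); loss <- c(0, 0.25, 0.5)
  upd2 <- gsbench:::adaboost_update_weights(D, loss)
  Lbar <- 0.2 * 0 + 0.3 * 0.25 + 0.5 * 0.5
  beta <- Lbar / (1 - Lbar)
  Draw <- D * beta^(1 - loss)
  expect_equal(upd2$Lbar, Lbar)
  expect_equal(upd2$D, Draw / sum(Draw), tolerance = 1e-12)
})

test_that("boosting weights remain a distribution every round", {
  sim <- ml_sim(n = 50L, seed = 9, noise = 2)
  fit <- fit_adaboost_r2(sim$X, sim$y,
                         adaboost_params(n_estimators = 8L, base = "krr",
                                         base_params = krr_params(lam = 1),
                                         seed = 5L))
  expect_gt(length(fit$D_history), 0L)
  for (D in fit$D_history) {
    expect_equal(sum(D), 1, tolerance = 1e-12)
    expect_true(all(D >= 0))
  }
})

test_that("one boosting round reduces to its single weak learner", {
  sim <- ml_sim(n = 40L, seed = 10)
  fit <- fit_adaboost_r2(sim$X, sim$y,
                         adaboost_params(n_estimators = 1L, base = "krr",
                                         seed = 6L))
  expect_length(fit$learners, 1L)
  expect_equal(predict(fit, sim$X), unname(predict(fit$learners[[1]], sim$X)))
})

test_that("identical weak learners yield their common prediction", {
  # constant response: every SVR learner sits flat inside the tube, so all
  # rounds produce the identical prediction and losses of exactly zero
  sim <- ml_sim(n = 30L, seed = 11)
  fit <- fit_adaboost_r2(sim$X, rep(2.5, 30),
                         adaboost_params(n_estimators = 4L, base = "svr",
                                         seed = 7L))
  expect_true(fit$perfect_learner)
  expect_length(fit$learners, 4L)
  expect_equal(predict(fit, sim$X), rep(2.5, 30))
})

test_that("the weighted median follows its defining infimum", {
  v <- c(3, 1, 2)
  w <- c(0.2, 0.5, 0.3)
  # cumulative weight in value order (1, 2, 3): 0.5, 0.8, 1.0 -> first >= 0.5 is 1
  expect_equal(gsbench:::weighted_median(v, w), 1)
  expect_equal(gsbench:::weighted_median(v, c(1, 1, 1)), 2)
})

test_that("grid search returns the argmax of its own score table", {
  sim <- ml_sim(n = 80L, p = 20L, seed = 12)
  grid <- tidyr::expand_grid(kernel = "rbf", lam = c(0.01, 0.1, 1),
                             gamma = c(1e-3, 1e-2))
  gs <- grid_search(sim$X, sim$y, "krr", grid = grid, seed = 3L)
  expect_equal(nrow(gs$table), 6L)
  expect_equal(gs$best_row$mean_r, max(gs$table$mean_r))
  expect_equal(gs$best$lam, gs$best_row$lam)
  # recomputation oracle: an independent rerun reproduces the winner
  gs2 <- grid_search(sim$X, sim$y, "krr", grid = grid, seed = 3L)
  expect_identical(gs$best_row, gs2$best_row)
  expect_equal(gs$table$mean_r, gs2$table$mean_r)
})

test_that("single-combination grids are returned as-is and ties prefer regularization", {
  sim <- ml_sim(n = 40L, seed = 13)
  one <- tibble::tibble(kernel = "rbf", lam = 0.5, gamma = 1e-3)
  gs <- grid_search(sim$X, sim$y, "krr", grid = one)
  expect_equal(gs$best$lam, 0.5)
  # an over-wide epsilon tube flattens every SVR: all scores tie at the
  # flagged 0 and the complexity order picks the smallest C
  wide <- tibble::tibble(kernel = "rbf", C = c(14, 7, 1), gamma = 1e-3,
                         epsilon = diff(range(sim$y)) * 2)
  gsd <- suppressWarnings(grid_search(sim$X, sim$y, "svr", grid = wide,
                                      seed = 4L))
  expect_true(all(gsd$table$mean_r == 0))
  expect_equal(gsd$best_row$C, 1)
  expect_error(grid_search(sim$X, sim$y, "krr", grid = one[0, ]), "empty")
})
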