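# Machine-learning regressors on genotype dosages: support vector regression
# (libsvm via e1071), kernel ridge regression (closed form), random forest
# (ranger) and Adaboost.R2 with SVR/KRR weak learners, plus grid search with
# internal five-fold cross-validation scored by Pearson correlation.
#
# Features are raw dosages 0/1/2 without standardization.

#' Hyperparameter containers for the ML regressors
#'
#' Defaults are the tuned optima of the cross-validation benchmark: SVR with
#' radial kernel, C = 7, gamma = 1e-4 (epsilon = 0.1); KRR with radial
#' kernel, lambda = 0.1, gamma = 1e-4; random forest with 250 trees of
#' unlimited depth; Adaboost.R2 with 50 boosting rounds.
#'
#' @param kernel `"rbf"` or `"linear"`.
#' @param C Positive regularization constant of the SVR loss.
#' @param gamma Positive radial-kernel bandwidth `exp(-gamma * ||x - x'||^2)`.
#' @param epsilon Half-width of the epsilon-insensitive tube.
#' @param lam Non-negative KRR ridge penalty (lambda).
#' @param n_estimators Number of trees (RF) or boosting rounds (Adaboost.R2).
#' @param max_depth Maximum tree depth; `Inf` for unlimited.
#' @param mtry Features tried per split; default all (bagged regression
#'   trees, matching the reference implementation's regression default).
#' @param base Weak learner for Adaboost.R2: `"svr"` or `"krr"`.
#' @param base_params [svr_params()] or [krr_params()] for the weak learner.
#' @param seed Integer seed for resampling-based learners.
#' @return A parameter object of the matching class.
#' @name ml_params
NULL

#' @rdname ml_params
#' @export
svr_params <- function(kernel = "rbf", C = 7, gamma = 1e-4, epsilon = 0.1) {
  kernel <- match.arg(kernel, c("rbf", "linear"))
  assert_scalar_num(C, "C", lower = 1e-12)
  assert_scalar_num(gamma, "gamma", lower = 1e-12)
  assert_scalar_num(epsilon, "epsilon", lower = 0)
  structure(list(kernel = kernel, C = C, gamma = gamma, epsilon = epsilon),
            class = "svr_params")
}

#' @rdname ml_params
#' @export
krr_params <- function(kernel = "rbf", lam = 0.1, gamma = 1e-4) {
  kernel <- match.arg(kernel, c("rbf", "linear"))
  assert_scalar_num(lam, "lam", lower = 0)
  assert_scalar_num(gamma, "gamma", lower = 1e-12)
  structure(list(kernel = kernel, lam = lam, gamma = gamma),
            class = "krr_params")
}

#' @rdname ml_params
#' @export
rf_params <- function(n_estimators = 250L, max_depth = Inf, mtry = NULL,
                      replace = TRUE, sample_fraction = 1, seed = 1L) {
  n_estimators <- assert_count(n_estimators, "n_estimators", 1L)
  structure(list(n_estimators = n_estimators, max_depth = max_depth,
                 mtry = mtry, replace = replace,
                 sample_fraction = sample_fraction, seed = as.integer(seed)),
            class = "rf_params")
}

#' @rdname ml_params
#' @export
adaboost_params <- function(n_estimators = 50L, base = c("krr", "svr"),
                            base_params = NULL, seed = 1L) {
  base <- match.arg(base)
  n_estimators <- assert_count(n_estimators, "n_estimators", 1L)
  if (is.null(base_params)) {
    base_params <- if (base == "svr") svr_params() else krr_params()
  }
  structure(list(n_estimators = n_estimators, base = base,
                 base_params = base_params, seed = as.integer(seed)),
            class = "adaboost_params")
}

kernel_matrix <- function(X1, X2, kernel, gamma) {
  if (kernel == "linear") return(tcrossprod(X1, X2))
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  exp(-gamma * pmax(d2, 0))
}

check_xy <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != length(y)) abort("rows of X must match length of y")
  if (anyNA(X) || any(!is.finite(X))) abort("non-finite features in X")
  if (anyNA(y) || any(!is.finite(y))) abort("non-finite response values")
  X
}

#' Support vector regression
#'
#' Epsilon-insensitive SVR in the dual form (libsvm). Prediction is the
#' support-vector expansion over kernel evaluations.
#'
#' @param X Training dosage matrix (animals x markers).
#' @param y Response vector (corrected phenotypes).
#' @param params An [svr_params()].
#' @return An object of class `svr_fit` with a `predict` method.
#' @export
fit_svr <- function(X, y, params = svr_params()) {
  X <- check_xy(X, y)
  fit <- e1071::svm(
    x = X, y = y, type = "eps-regression",
    kernel = if (params$kernel == "rbf") "radial" else "linear",
    cost = params$C, gamma = params$gamma, epsilon = params$epsilon,
    scale = FALSE, fitted = FALSE
  )
  structure(list(params = params, svm = fit, n_train = nrow(X),
                 mean_y = mean(y)),
            class = "svr_fit")
}

#' @export
predict.svr_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$svm$tot.nSV == 0L) {
    # every training point inside the epsilon tube: the flat solution
    return(rep(object$mean_y, nrow(newdata)))
  }
  unname(predict(object$svm, newdata))
}

#' Kernel ridge regression
#'
#' Closed-form dual solution `alpha = (K + lambda I)^-1 y`; prediction for a
#' new sample is `k' alpha` with `k` the vector of kernel evaluations against
#' the training samples.
#'
#' @inheritParams fit_svr
#' @param params A [krr_params()].
#' @return An object of class `krr_fit` with a `predict` method.
#' @export
fit_krr <- function(X, y, params = krr_params()) {
  X <- check_xy(X, y)
  K <- kernel_matrix(X, X, params$kernel, params$gamma)
  alpha <- tryCatch(
    solve(K + diag(params$lam, nrow(X)), y),
    error = function(e) abort("K + lambda*I is numerically singular; increase `lam`")
  )
  structure(list(params = params, X = X, alpha = as.numeric(alpha)),
            class = "krr_fit")
}

#' @export
predict.krr_fit <- function(object, newdata, ...) {
  k <- kernel_matrix(as.matrix(newdata), object$X, object$params$kernel,
                     object$params$gamma)
  drop(k %*% object$alpha)
}

#' Random forest regression
#'
#' An ensemble of CART regression trees grown on bootstrap resamples;
#' the prediction is the arithmetic mean of the tree predictions.
#'
#' @inheritParams fit_svr
#' @param params An [rf_params()].
#' @return An object of class `rf_fit` with a `predict` method.
#' @export
fit_rf <- function(X, y, params = rf_params()) {
  X <- check_xy(X, y)
  colnames(X) <- colnames(X) %||% sprintf("x%d", seq_len(ncol(X)))
  fit <- ranger::ranger(
    x = X, y = y,
    num.trees = params$n_estimators,
    max.depth = if (is.finite(params$max_depth)) params$max_depth else NULL,
    mtry = params$mtry %||% ncol(X),
    replace = params$replace %||% TRUE,
    sample.fraction = params$sample_fraction %||% 1,
    seed = params$seed,
    num.threads = 1L
  )
  structure(list(params = params, forest = fit, features = colnames(X)),
            class = "rf_fit")
}

#' @export
predict.rf_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$features
  predict(object$forest, data = newdata, num.threads = 1L)$predictions
}

# One Adaboost.R2 weight update (Drucker's linear loss). Exposed internally
# for direct arithmetic checks.
#  loss_i = |y_i - f(x_i)| / max_i |y_i - f(x_i)|
#  Lbar   = sum_i loss_i D_i;  beta = Lbar / (1 - Lbar)
#  D'_i  propto D_i * beta^(1 - loss_i)
adaboost_update_weights <- function(D, loss, eps_floor = 1e-10) {
  Lbar <- sum(loss * D)
  beta <- max(Lbar / (1 - Lbar), eps_floor)
  Dnew <- D * beta^(1 - loss)
  list(D = Dnew / sum(Dnew), beta = beta, Lbar = Lbar)
}

# Weighted median: inf{ v : sum of weights of predictions <= v reaches half
# the total weight }.
weighted_median <- function(values, weights) {
  o <- order(values)
  cw <- cumsum(weights[o])
  values[o][which(cw >= 0.5 * sum(weights))[1]]
}

#' Adaboost.R2 regression
#'
#' Boosting for regression: each round fits the weak learner on a weighted
#' bootstrap resample (size n, probabilities `D_t`), computes the linear
#' loss `L_t(i) = |y_i - f_t(x_i)| / max_i |y_i - f_t(x_i)|`, the average
#' loss `Lbar_t = sum_i L_t(i) D_t(i)` and `beta_t = Lbar_t / (1 - Lbar_t)`,
#' reweights `D_{t+1}(i) = D_t(i) beta_t^(1 - L_t(i)) / Z_t`, and stops early
#' when `Lbar_t >= 0.5`. The ensemble predicts with the weighted median of
#' the weak learners with weights `log(1 / beta_t)`. A perfect weak learner
#' (all losses zero) has `beta_t` floored at 1e-10 and dominates the median;
#' the fit is flagged.
#'
#' @inheritParams fit_svr
#' @param params An [adaboost_params()].
#' @return An object of class `adaboost_fit` with a `predict` method.
#' @export
fit_adaboost_r2 <- function(X, y, params = adaboost_params()) {
  X <- check_xy(X, y)
  n <- nrow(X)
  fit_base <- function(Xb, yb) {
    if (params$base == "svr") fit_svr(Xb, yb, params$base_params)
    else fit_krr(Xb, yb, params$base_params)
  }
  learners <- list()
  betas <- numeric()
  D_history <- list()
  perfect <- FALSE
  D <- rep(1 / n, n)
  with_seed(params$seed, {
    for (t in seq_len(params$n_estimators)) {
      idx <- sample.int(n, n, replace = TRUE, prob = D)
      lrn <- fit_base(X[idx, , drop = FALSE], y[idx])
      pred <- predict(lrn, X)
      abs_err <- abs(y - pred)
      emax <- max(abs_err)
      loss <- if (emax > 0) abs_err / emax else rep(0, n)
      upd <- adaboost_update_weights(D, loss)
      if (upd$Lbar >= 0.5) {
        if (length(learners) == 0L) {
          learners[[1L]] <- lrn
          betas[1L] <- upd$beta
        }
        break
      }
      if (upd$Lbar == 0) perfect <- TRUE
      learners[[t]] <- lrn
      betas[t] <- upd$beta
      D <- upd$D
      D_history[[t]] <- D
    }
  })
  structure(list(params = params, learners = learners, betas = betas,
                 weights = log(1 / betas), D_history = D_history,
                 perfect_learner = perfect),
            class = "adaboost_fit")
}

#' @export
predict.adaboost_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  preds <- vapply(object$learners, function(l) predict(l, newdata),
                  numeric(nrow(newdata)))
  preds <- matrix(preds, nrow = nrow(newdata))
  apply(preds, 1L, weighted_median, weights = object$weights)
}

# ---- grid search -----------------------------------------------------------

ml_param_object <- function(method, row) {
  switch(method,
    svr = svr_params(kernel = row$kernel %||% "rbf", C = row$C,
                     gamma = row$gamma, epsilon = row$epsilon %||% 0.1),
    krr = krr_params(kernel = row$kernel %||% "rbf", lam = row$lam,
                     gamma = row$gamma),
    rf = rf_params(n_estimators = row$n_estimators,
                   max_depth = row$max_depth %||% Inf,
                   seed = row$seed %||% 1L),
    adaboost_svr = adaboost_params(
      n_estimators = row$n_estimators, base = "svr",
      base_params = svr_params(kernel = row$kernel %||% "rbf", C = row$C,
                               gamma = row$gamma),
      seed = row$seed %||% 1L),
    adaboost_krr = adaboost_params(
      n_estimators = row$n_estimators, base = "krr",
      base_params = krr_params(kernel = row$kernel %||% "rbf", lam = row$lam,
                               gamma = row$gamma),
      seed = row$seed %||% 1L),
    abort(sprintf("unknown ML method `%s`", method))
  )
}

ml_fit <- function(method, X, y, params) {
  switch(method,
    svr = fit_svr(X, y, params),
    krr = fit_krr(X, y, params),
    rf = fit_rf(X, y, params),
    adaboost_svr = ,
    adaboost_krr = fit_adaboost_r2(X, y, params)
  )
}

#' Default hyperparameter grids
#'
#' Grid lattices spanning the tuned optima of both the cross-validation and
#' the forward-prediction benchmarks.
#'
#' @param method One of `"svr"`, `"krr"`, `"rf"`, `"adaboost_svr"`,
#'   `"adaboost_krr"`.
#' @return A tibble, one row per hyperparameter combination.
#' @export
default_grid <- function(method = c("svr", "krr", "rf", "adaboost_svr",
                                    "adaboost_krr")) {
  method <- match.arg(method)
  Cs <- c(1, 3, 5, 7, 10, 14)
  gammas <- c(1e-6, 1e-5, 5e-5, 1e-4, 1e-3)
  lams <- c(0.01, 0.07, 0.1, 0.9, 1)
  switch(method,
    svr = tidyr::expand_grid(kernel = "rbf", C = Cs, gamma = gammas),
    krr = tidyr::expand_grid(kernel = "rbf", lam = lams, gamma = gammas),
    rf = tidyr::expand_grid(n_estimators = c(100, 250, 400, 430, 500),
                            max_depth = c(Inf, 5, 10)),
    adaboost_svr = tidyr::expand_grid(n_estimators = c(50, 60, 70),
                                      kernel = "rbf", C = 7, gamma = gammas),
    adaboost_krr = tidyr::expand_grid(n_estimators = c(50, 60, 70),
                                      kernel = "rbf", lam = lams, gamma = gammas)
  )
}

# Complexity ordering used for tie-breaking: prefer stronger regularization
# (smaller C, larger lambda, fewer trees/rounds, shallower trees).
grid_order <- function(grid, method) {
  key <- switch(method,
    svr = order(grid$C, grid$gamma),
    krr = order(-grid$lam, grid$gamma),
    rf = order(grid$n_estimators, grid$max_depth),
    adaboost_svr = order(grid$n_estimators, grid$C %||% rep(0, nrow(grid)),
                         grid$gamma),
    adaboost_krr = order(grid$n_estimators,
                         -(grid$lam %||% rep(0, nrow(grid))), grid$gamma)
  )
  key
}

#' Grid search with internal five-fold cross-validation
#'
#' Scores every hyperparameter combination by the mean Pearson correlation
#' between held-out responses and predictions over an internal 5-fold split
#' of the training data, and returns the best combination with the full
#' score table. An inner fold with zero-variance predictions scores 0 for
#' that fold (with a warning). Ties are broken towards stronger
#' regularization (smaller C, larger lambda, fewer trees).
#'
#' @param X Training dosage matrix.
#' @param y Training response.
#' @param method ML method tag (see [default_grid()]).
#' @param grid Tibble of hyperparameter combinations; defaults to
#'   [default_grid()].
#' @param n_folds Number of inner folds.
#' @param seed Seed for the inner fold split.
#' @return List with `best` (parameter object), `best_row` (tibble row) and
#'   `table` (score table with `mean_r`).
#' @export
grid_search <- function(X, y, method, grid = NULL, n_folds = 5L, seed = 1L) {
  method <- match.arg(method, c("svr", "krr", "rf", "adaboost_svr", "adaboost_krr"))
  grid <- grid %||% default_grid(method)
  if (nrow(grid) == 0L) abort("empty hyperparameter grid")
  X <- check_xy(X, y)
  n <- nrow(X)
  if (n_folds > n) abort("more inner folds than training samples")
  folds <- with_seed(derive_seed(seed, "inner-cv"), {
    sample(rep_len(seq_len(n_folds), n))
  })
  score_one <- function(row) {
    params <- ml_param_object(method, as.list(row))
    rs <- vapply(seq_len(n_folds), function(k) {
      tr <- folds != k
      fit <- ml_fit(method, X[tr, , drop = FALSE], y[tr], params)
      pred <- predict(fit, X[!tr, , drop = FALSE])
      if (sd(pred) < 1e-12 || sd(y[!tr]) < 1e-12) {
        warn("zero-variance predictions in an inner fold; correlation set to 0")
        0
      } else {
        cor(y[!tr], pred)
      }
    }, numeric(1))
    mean(rs)
  }
  ord <- grid_order(grid, method)
  grid_ordered <- grid[ord, , drop = FALSE]
  scores <- vapply(seq_len(nrow(grid_ordered)),
                   function(i) score_one(grid_ordered[i, ]), numeric(1))
  best_i <- which.max(scores)
  table <- dplyr::mutate(grid_ordered, mean_r = scores)
  list(
    best = ml_param_object(method, as.list(grid_ordered[best_i, ])),
    best_row = table[best_i, , drop = FALSE],
    table = table
  )
}
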