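# GBLUP and single-step GBLUP prediction of corrected phenotypes.
#
# Model: y_c = 1*mu + Z g + e, g ~ N(0, K sigma2_g), e ~ N(0, I sigma2_e),
# with K = G (GBLUP, genotyped animals) or K = H (ssGBLUP, all pedigree
# animals). Variance components are re-estimated on the reference set of each
# fold by REML; validation animals stay in K but their phenotype rows are
# removed, and their prediction is PV = mu_hat + gebv.

# Restricted log-likelihood profile in lambda = sigma2_e / sigma2_g through
# the MME built from the precision matrix K^-1 (works for sparse H^-1 and
# dense G^-1 alike). Returns the profiled -2 logLR up to a constant.
kernel_mme_profile <- function(y, ref_pos, Kinv, lambda) {
  N <- nrow(Kinv)
  n <- length(y)
  z1 <- numeric(N); z1[ref_pos] <- 1
  ZtZ <- Matrix::Diagonal(N, z1)
  Zty <- numeric(N); Zty[ref_pos] <- y
  M <- rbind(
    cbind(Matrix::Matrix(n, 1, 1), Matrix::Matrix(z1, 1, N)),
    cbind(Matrix::Matrix(z1, N, 1), ZtZ + Kinv * lambda)
  )
  M <- Matrix::forceSymmetric(M)
  Ch <- Matrix::Cholesky(methods::as(M, "CsparseMatrix"), LDL = FALSE, perm = TRUE)
  rhs <- c(sum(y), Zty)
  sol <- as.numeric(Matrix::solve(Ch, rhs))
  qform <- sum(y * y) - sum(sol * rhs)
  logdetM <- 2 * as.numeric(Matrix::determinant(Ch, sqrt = TRUE)$modulus)
  s2e <- qform / (n - 1)
  m2ll <- (n - 1) * (log(s2e) + 1) - N * log(lambda) + logdetM
  list(m2ll = m2ll, s2e = s2e, sol = sol)
}

# Core fit shared by GBLUP and ssGBLUP.
kernel_blup_fit <- function(yc, Kinv, reference_ids, method, vc = NULL) {
  ids <- rownames(Kinv)
  if (!all(reference_ids %in% ids)) {
    abort(sprintf("%d reference animals are absent from the relationship matrix",
                  sum(!reference_ids %in% ids)))
  }
  yref <- yc$y_c[match(reference_ids, yc$animal)]
  if (anyNA(yref)) abort("corrected phenotypes missing for some reference animals")
  ref_pos <- match(reference_ids, ids)
  n <- length(yref)
  if (sd(yref) < 1e-12) {
    warn("reference corrected phenotypes are constant; genomic variance at boundary")
    lambda <- 1e8
    prof <- kernel_mme_profile(yref, ref_pos, Kinv, lambda)
    s2e <- max(prof$s2e, 1e-12)
  } else if (!is.null(vc)) {
    lambda <- vc$sigma2_e / vc$sigma2_g
    prof <- kernel_mme_profile(yref, ref_pos, Kinv, lambda)
    s2e <- vc$sigma2_e
  } else {
    obj <- function(loglam) kernel_mme_profile(yref, ref_pos, Kinv, exp(loglam))$m2ll
    opt <- optimize(obj, interval = c(-10, 12), tol = 1e-7)
    lambda <- exp(opt$minimum)
    prof <- kernel_mme_profile(yref, ref_pos, Kinv, lambda)
    s2e <- prof$s2e
  }
  mu <- prof$sol[1]
  gebv <- prof$sol[-1]
  structure(
    list(
      method = method,
      mu_hat = mu,
      predictions = tibble::tibble(animal = ids, gebv = gebv, pv = mu + gebv),
      vc_used = list(sigma2_g = s2e / lambda, sigma2_e = s2e, lambda = lambda),
      n_reference = n
    ),
    class = "genomic_fit"
  )
}

#' @export
print.genomic_fit <- function(x, ...) {
  cat(sprintf("<genomic_fit> %s: %d animals (%d reference)\n", x$method,
              nrow(x$predictions), x$n_reference))
  cat(sprintf("  mu = %.4f  sigma2_g = %.4f  sigma2_e = %.4f\n",
              x$mu_hat, x$vc_used$sigma2_g, x$vc_used$sigma2_e))
  invisible(x)
}

#' GBLUP prediction
#'
#' Estimates `sigma2_g`/`sigma2_e` by REML on the reference animals
#' (eigendecomposition profile likelihood), then computes the joint BLUP of
#' all animals in `G` from the reference phenotypes. The solution is the one
#' of the mixed-model equations with penalty `sigma2_e / sigma2_g`; it is
#' evaluated through the equivalent covariance form
#' `gebv = sigma2_g G[, ref] V^-1 (y - mu_hat)`, which also covers a
#' positive semi-definite (e.g. unblended) `G`. Every animal in `G` receives
#' a GEBV and a predicted value `PV = mu_hat + gebv`.
#'
#' @param yc Corrected phenotypes tibble (`animal`, `y_c`).
#' @param G Genomic relationship matrix (PSD; blending is only needed when a
#'   downstream step requires strict invertibility).
#' @param reference_ids Animals whose phenotypes are used for training.
#' @param vc Optional list with `sigma2_g` and `sigma2_e` to skip REML.
#' @return A `genomic_fit`.
#' @export
fit_gblup <- function(yc, G, reference_ids, vc = NULL) {
  check_square_named(G, "G")
  ids <- rownames(G)
  if (!all(reference_ids %in% ids)) {
    abort(sprintf("%d reference animals are absent from G",
                  sum(!reference_ids %in% ids)))
  }
  yref <- yc$y_c[match(reference_ids, yc$animal)]
  if (anyNA(yref)) abort("corrected phenotypes missing for some reference animals")
  n <- length(yref)
  Grr <- G[reference_ids, reference_ids, drop = FALSE]
  if (sd(yref) < 1e-12) {
    warn("reference corrected phenotypes are constant; genomic variance at boundary")
    est <- list(sigma2_g = 1e-12 * max(mean(diag(Grr)), 1),
                sigma2_e = max(var(yref), 1e-12), lambda = 1e12)
  } else if (!is.null(vc)) {
    est <- list(sigma2_g = vc$sigma2_g, sigma2_e = vc$sigma2_e,
                lambda = vc$sigma2_e / vc$sigma2_g)
  } else {
    est <- reml_kernel_eigen(yref, Grr)
  }
  V <- est$sigma2_g * Grr + diag(est$sigma2_e, n)
  Vi_y <- solve(V, cbind(yref, 1))
  mu <- sum(Vi_y[, 1]) / sum(Vi_y[, 2])
  w <- solve(V, yref - mu)
  gebv <- est$sigma2_g * drop(G[, reference_ids, drop = FALSE] %*% w)
  structure(
    list(
      method = "GBLUP",
      mu_hat = mu,
      predictions = tibble::tibble(animal = ids, gebv = gebv, pv = mu + gebv),
      vc_used = est,
      n_reference = n
    ),
    class = "genomic_fit"
  )
}

#' Single-step GBLUP prediction
#'
#' Same mixed-model equations as GBLUP with the single-step `H^-1` in place
#' of `G^-1`, over the full pedigree id set, so that non-genotyped animals
#' with corrected phenotypes contribute to the reference.
#'
#' @param yc Corrected phenotypes tibble (`animal`, `y_c`).
#' @param H_inv Single-step H-inverse from [build_H_inverse()] or
#'   [single_step_matrices()].
#' @param reference_ids Reference animals (may include non-genotyped ones).
#' @param vc Optional list with `sigma2_g` and `sigma2_e` to skip REML.
#' @return A `genomic_fit`.
#' @export
fit_ssgblup <- function(yc, H_inv, reference_ids, vc = NULL) {
  check_square_named(H_inv, "H_inv")
  kernel_blup_fit(yc, H_inv, reference_ids, method = "ssGBLUP", vc = vc)
}

# Independent eigen-decomposition REML (EMMA-style) used as a cross-check of
# the MME profile route in the tests.
reml_kernel_eigen <- function(y, K) {
  n <- length(y)
  S <- diag(n) - matrix(1 / n, n, n)
  eig <- eigen(S %*% K %*% S, symmetric = TRUE)
  xi <- eig$values[seq_len(n - 1)]
  eta <- drop(crossprod(eig$vectors[, seq_len(n - 1)], y))
  obj <- function(logd) {
    d <- exp(logd)
    s2e <- sum(eta^2 / (d * xi + 1)) / (n - 1)
    sum(log(d * xi + 1)) + (n - 1) * log(s2e)
  }
  opt <- optimize(obj, c(-12, 10), tol = 1e-9)
  d <- exp(opt$minimum)
  s2e <- sum(eta^2 / (d * xi + 1)) / (n - 1)
  list(sigma2_g = d * s2e, sigma2_e = s2e, lambda = 1 / d)
}
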