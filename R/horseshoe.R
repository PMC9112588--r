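# Horseshoe-prior Bayesian marker regression (BayesHE-style) for corrected
# phenotypes, fitted by Gibbs sampling.

#' Horseshoe chain configuration
#'
#' The `"paper"` preset runs 50,000 cycles with a 20,000-cycle burn-in and
#' every 50th sample of the remaining 30,000 retained (600 posterior draws).
#' The `"test"` preset (5,000 / 2,000 / 5) keeps chains desk-scale fast.
#'
#' @param n_iter,burn_in,thin Chain length, burn-in, thinning interval.
#' @param seed Integer seed for the chain.
#' @param preset Optional `"paper"` or `"test"` shortcut overriding the
#'   numeric arguments.
#' @return An `hs_config` object.
#' @export
hs_config <- function(n_iter = 50000L, burn_in = 20000L, thin = 50L, seed = 1L,
                      preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("paper", "test"))
    if (preset == "paper") { n_iter <- 50000L; burn_in <- 20000L; thin <- 50L }
    if (preset == "test") { n_iter <- 5000L; burn_in <- 2000L; thin <- 5L }
  }
  n_iter <- assert_count(n_iter, "n_iter", 1L)
  burn_in <- assert_count(burn_in, "burn_in", 0L)
  thin <- assert_count(thin, "thin", 1L)
  if (burn_in >= n_iter) abort("`burn_in` must be smaller than `n_iter`")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed),
                 n_kept = (n_iter - burn_in) %/% thin),
            class = "hs_config")
}

#' Fit the horseshoe marker regression
#'
#' Gibbs sampler for `y_c = 1 mu + X beta + e` with the horseshoe hierarchy
#' `beta_j ~ N(0, lambda_j^2 tau^2 sigma2_e)`, `lambda_j ~ half-Cauchy(0,1)`,
#' `tau ~ half-Cauchy(0,1)`, a flat prior on `mu` and a scaled-inverse-chi-
#' square prior on `sigma2_e`. Half-Cauchy scales are sampled via
#' inverse-gamma auxiliary variables. Genotypes are centered by the training
#' allele frequencies; monomorphic training markers carry no information and
#' their effects are fixed at zero. Posterior means over retained draws give
#' marker effects; `PV = mu_post + x' beta_post` for every animal in `geno`.
#'
#' @param yc Corrected phenotypes tibble (`animal`, `y_c`).
#' @param geno `geno_matrix` (or dosage matrix) with complete dosages for all
#'   animals to be predicted.
#' @param reference_ids Training animals (must have `y_c` and genotypes);
#'   at least 20.
#' @param cfg An [hs_config()].
#' @param save_beta Keep the full matrix of retained marker-effect draws
#'   (needed for per-marker Monte-Carlo diagnostics).
#' @param nu0,s0 Degrees of freedom and scale of the residual-variance prior;
#'   the default centers the prior loosely on half the phenotypic variance.
#' @return An `hs_fit` with `mu_post`, `beta_post`, `sigma2e_post`,
#'   predictions for all animals and effective-sample-size diagnostics.
#' @export
fit_bayeshe <- function(yc, geno, reference_ids, cfg = hs_config(preset = "test"),
                        save_beta = FALSE, nu0 = 5, s0 = NULL) {
  stopifnot(inherits(cfg, "hs_config"))
  dos <- if (inherits(geno, "geno_matrix")) geno$dosage else geno
  if (anyNA(dos)) abort("horseshoe regression needs complete dosages")
  if (!all(reference_ids %in% rownames(dos))) {
    abort("reference animals missing from the genotype matrix")
  }
  yref <- yc$y_c[match(reference_ids, yc$animal)]
  if (anyNA(yref) || any(!is.finite(yref))) {
    abort("non-finite corrected phenotypes in the reference set")
  }
  if (length(yref) < 20L) abort("need at least 20 reference animals")
  Xref <- dos[reference_ids, , drop = FALSE]
  ctr <- colMeans(Xref)
  Xc <- sweep(Xref, 2L, ctr, "-")
  vy <- var(yref)
  if (is.null(s0)) s0 <- max(vy / 2, 1e-8)
  res <- with_seed(cfg$seed, {
    .horseshoe_gibbs(yref, Xc, cfg$n_iter, cfg$burn_in, cfg$thin,
                     nu0, s0, save_beta)
  })
  beta <- as.numeric(res$beta_post)
  mu <- mean(res$mu)
  Xall <- sweep(dos, 2L, ctr, "-")
  gebv <- drop(Xall %*% beta)
  diagnostics <- tibble::tibble(
    parameter = c("mu", "sigma2e", "tau2"),
    ess = c(ess(res$mu), ess(res$sigma2e), ess(res$tau2))
  )
  structure(
    list(
      method = "BayesHE",
      mu_post = mu,
      beta_post = tibble::tibble(marker = colnames(dos), beta = beta),
      sigma2e_post = mean(res$sigma2e),
      tau2_post = mean(res$tau2),
      predictions = tibble::tibble(animal = rownames(dos), gebv = gebv,
                                   pv = mu + gebv),
      diagnostics = diagnostics,
      draws = list(mu = as.numeric(res$mu), sigma2e = as.numeric(res$sigma2e),
                   tau2 = as.numeric(res$tau2),
                   beta = if (save_beta) res$beta_draws else NULL),
      n_kept = res$n_kept,
      config = cfg,
      center = ctr
    ),
    class = "hs_fit"
  )
}

#' @export
print.hs_fit <- function(x, ...) {
  cat(sprintf("<hs_fit> horseshoe regression: %d markers, %d retained draws\n",
              nrow(x$beta_post), x$n_kept))
  cat(sprintf("  mu = %.4f  sigma2e = %.4f  tau2 = %.3g\n",
              x$mu_post, x$sigma2e_post, x$tau2_post))
  invisible(x)
}

# Effective sample size by initial positive sequence of autocorrelations
# (Geyer); small, dependency-free.
ess <- function(x) {
  n <- length(x)
  if (n < 4L || sd(x) == 0) return(as.numeric(n))
  rho <- acf(x, lag.max = min(n - 2L, 200L), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq(1L, length(rho) - 1L, by = 2L)) {
    pair <- rho[k] + rho[k + 1L]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
  }
  n / (1 + 2 * s)
}
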