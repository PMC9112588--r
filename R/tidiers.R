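# broom-style tidiers for the fitted objects.

#' Tidy a variance-component fit
#'
#' @param x A `varcomp`.
#' @param ... Unused.
#' @return One row per variance component with `component` and `estimate`.
#' @export
tidy.varcomp <- function(x, ...) {
  tibble::tibble(
    component = c("sigma2_a", "sigma2_pe", "sigma2_e"),
    estimate = c(x$sigma2_a, x$sigma2_pe, x$sigma2_e)
  )
}

#' @rdname tidy.varcomp
#' @export
glance.varcomp <- function(x, ...) {
  tibble::tibble(h2 = x$h2, se_h2 = x$se_h2, repeatability = x$repeatability,
                 logLik = x$loglik, converged = x$converged, n_iter = x$n_iter)
}

#' Tidy a GBLUP / ssGBLUP fit
#'
#' @param x A `genomic_fit`.
#' @param ... Unused.
#' @return Per-animal GEBVs and predicted values.
#' @export
tidy.genomic_fit <- function(x, ...) x$predictions

#' @rdname tidy.genomic_fit
#' @export
glance.genomic_fit <- function(x, ...) {
  tibble::tibble(method = x$method, mu_hat = x$mu_hat,
                 sigma2_g = x$vc_used$sigma2_g, sigma2_e = x$vc_used$sigma2_e,
                 lambda = x$vc_used$lambda, n_reference = x$n_reference)
}

#' Tidy a horseshoe fit
#'
#' @param x An `hs_fit`.
#' @param ... Unused.
#' @return Per-marker posterior mean effects.
#' @export
tidy.hs_fit <- function(x, ...) x$beta_post

#' @rdname tidy.hs_fit
#' @export
glance.hs_fit <- function(x, ...) {
  tibble::tibble(mu_post = x$mu_post, sigma2e_post = x$sigma2e_post,
                 tau2_post = x$tau2_post, n_kept = x$n_kept)
}

#' Tidy a benchmark result
#'
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @return The per-fold metric table.
#' @export
tidy.benchmark_result <- function(x, ...) x$metrics

#' @rdname tidy.benchmark_result
#' @export
glance.benchmark_result <- function(x, ...) x$summary

#' Tidy a BLUP solution
#'
#' @param x A `blup_solution`.
#' @param ... Unused.
#' @return Per-animal EBVs.
#' @export
tidy.blup_solution <- function(x, ...) x$ebv
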