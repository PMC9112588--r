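# Pedigree repeatability model: average-information REML, Henderson's mixed
# model equations, and corrected phenotypes.
#
# Model: y = Xb + Za a + Zpe pe + e with a ~ N(0, A sigma2_a),
# pe ~ N(0, I sigma2_pe), e ~ N(0, I sigma2_e); b = herd-year-season effects.
#
# The restricted likelihood is evaluated through the mixed-model equations:
#   -2 logLR = n log s2e + qa log s2a + log|A| + qpe log s2pe + log|M| + y'Py
# with M the full (R^-1-scaled) MME coefficient matrix. Gradients use the
# standard trace identities tr(A^-1 Caa) and tr(Cpe,pe), computed from the
# sparse Cholesky factor of M; the AI matrix uses the working vectors
# Za*ahat/s2a, Zpe*pehat/s2pe, ehat/s2e.

#' Variance components of the repeatability model
#'
#' @param sigma2_a,sigma2_pe,sigma2_e Additive, permanent-environment and
#'   residual variances (all >= 0, residual > 0).
#' @param se_h2 Optional standard error of the heritability.
#' @param converged,n_iter,loglik Optimizer bookkeeping.
#' @return A `varcomp` object.
#' @export
variance_components <- function(sigma2_a, sigma2_pe, sigma2_e, se_h2 = NA_real_,
                                converged = NA, n_iter = NA_integer_,
                                loglik = NA_real_) {
  assert_scalar_num(sigma2_a, "sigma2_a", lower = 0)
  assert_scalar_num(sigma2_pe, "sigma2_pe", lower = 0)
  assert_scalar_num(sigma2_e, "sigma2_e", lower = 0)
  tot <- sigma2_a + sigma2_pe + sigma2_e
  structure(
    list(sigma2_a = sigma2_a, sigma2_pe = sigma2_pe, sigma2_e = sigma2_e,
         h2 = if (tot > 0) sigma2_a / tot else NA_real_,
         repeatability = if (tot > 0) (sigma2_a + sigma2_pe) / tot else NA_real_,
         se_h2 = se_h2, converged = converged, n_iter = n_iter, loglik = loglik),
    class = "varcomp"
  )
}

#' @export
print.varcomp <- function(x, ...) {
  cat("<varcomp> repeatability animal model\n")
  cat(sprintf("  sigma2_a = %.4f  sigma2_pe = %.4f  sigma2_e = %.4f\n",
              x$sigma2_a, x$sigma2_pe, x$sigma2_e))
  cat(sprintf("  h2 = %.4f%s   converged = %s (%s iterations)\n", x$h2,
              if (is.finite(x$se_h2)) sprintf(" (SE %.4f)", x$se_h2) else "",
              x$converged, x$n_iter))
  invisible(x)
}

# ---- design construction ---------------------------------------------------

validate_records <- function(ped, records) {
  if (!all(c("animal", "hys", "value") %in% names(records))) {
    abort("records need columns `animal`, `hys`, `value`")
  }
  missing_ids <- setdiff(unique(records$animal), ped$animal)
  if (length(missing_ids)) {
    abort(sprintf("record animals absent from pedigree: %s",
                  paste(head(missing_ids, 5L), collapse = ", ")))
  }
  if ("parity" %in% names(records) &&
      anyDuplicated(records[, c("animal", "parity")])) {
    abort("duplicated (animal, parity) records")
  }
  if (is.factor(records$hys)) {
    empty <- levels(records$hys)[tabulate(records$hys, nbins = nlevels(records$hys)) == 0L]
    if (length(empty)) {
      abort(sprintf("herd-year-season level(s) without records: %s",
                    paste(empty, collapse = ", ")))
    }
    droplevels(records$hys)
  } else {
    factor(records$hys)
  }
}

# Sparse designs and precomputed cross-products for the repeatability MME.
repeatability_design <- function(ped, records) {
  hys <- validate_records(ped, records)
  n <- nrow(records)
  y <- as.numeric(records$value)
  p <- nlevels(hys)
  animals <- ped$animal
  qa <- length(animals)
  rec_animal <- match(records$animal, animals)
  pe_ids <- sort(unique(records$animal))
  qpe <- length(pe_ids)
  rec_pe <- match(records$animal, pe_ids)
  X <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(hys), x = 1,
                            dims = c(n, p))
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = rec_animal, x = 1,
                             dims = c(n, qa))
  Zpe <- Matrix::sparseMatrix(i = seq_len(n), j = rec_pe, x = 1,
                              dims = c(n, qpe))
  W <- cbind(X, Za, Zpe)
  Ainv <- build_A_inverse(ped)
  pidx <- parent_index(ped)
  # A^-1 = T' D^-1 T with T = I - P/2: used for the trace tr(A^-1 Caa) through
  # the Cholesky factor of the MME (Frobenius norm of a triangular solve).
  f <- .inbreeding_ml(pidx$sire, pidx$dam)
  fs <- ifelse(pidx$sire > 0L, f[pmax(pidx$sire, 1L)], 0)
  fd <- ifelse(pidx$dam > 0L, f[pmax(pidx$dam, 1L)], 0)
  dmend <- ifelse(pidx$sire > 0L & pidx$dam > 0L, 0.5 - 0.25 * (fs + fd),
           ifelse(pidx$sire > 0L | pidx$dam > 0L, 0.75 - 0.25 * (fs + fd), 1))
  ii <- c(seq_len(qa), which(pidx$sire > 0L), which(pidx$dam > 0L))
  jj <- c(seq_len(qa), pidx$sire[pidx$sire > 0L], pidx$dam[pidx$dam > 0L])
  xx <- c(rep(1, qa), rep(-0.5, sum(pidx$sire > 0L) + sum(pidx$dam > 0L)))
  Tmat <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(qa, qa))
  U <- Matrix::Diagonal(x = 1 / sqrt(dmend)) %*% Tmat
  list(
    y = y, n = n, p = p, qa = qa, qpe = qpe,
    hys_levels = levels(hys),
    animals = animals, pe_ids = pe_ids,
    W = W, WtW = Matrix::crossprod(W), Wty = as.numeric(Matrix::crossprod(W, y)),
    yty = sum(y * y),
    Ainv = Ainv, logdetA = attr(Ainv, "logdet"), U = U,
    ix_f = seq_len(p), ix_a = p + seq_len(qa), ix_pe = p + qa + seq_len(qpe),
    records = records
  )
}

# Full MME coefficient matrix at given variance components.
mme_matrix <- function(ws, vc) {
  prior <- Matrix::bdiag(
    Matrix::Diagonal(ws$p, 0),
    ws$Ainv / vc$sigma2_a,
    Matrix::Diagonal(ws$qpe, 1 / vc$sigma2_pe)
  )
  Matrix::forceSymmetric(ws$WtW / vc$sigma2_e + prior)
}

# Restricted log-likelihood (up to an additive constant) plus solution pieces.
reml_loglik_pieces <- function(ws, vc, Ch = NULL) {
  M <- mme_matrix(ws, vc)
  Ch <- if (is.null(Ch)) Matrix::Cholesky(M, LDL = FALSE, perm = TRUE) else
    Matrix::update(Ch, M)
  rhs <- ws$Wty / vc$sigma2_e
  sol <- as.numeric(Matrix::solve(Ch, rhs))
  yPy <- (ws$yty - sum(sol * ws$Wty)) / vc$sigma2_e
  logdetM <- 2 * as.numeric(Matrix::determinant(Ch, sqrt = TRUE)$modulus)
  m2ll <- ws$n * log(vc$sigma2_e) + ws$qa * log(vc$sigma2_a) + ws$logdetA +
    ws$qpe * log(vc$sigma2_pe) + logdetM + yPy
  list(Ch = Ch, sol = sol, yPy = yPy, loglik = -0.5 * m2ll)
}

# tr(A^-1 Caa) and tr(Cpe,pe) from the Cholesky factor of M, in column chunks.
mme_traces <- function(ws, Ch, chunk = 512L) {
  ntot <- ws$p + ws$qa + ws$qpe
  # columns of B: [U' in animal rows | identity in pe rows]
  Ut <- Matrix::t(ws$U)
  tr_a <- 0
  for (start in seq(1L, ws$qa, by = chunk)) {
    cols <- start:min(start + chunk - 1L, ws$qa)
    B <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(ntot, length(cols)))
    B[ws$ix_a, ] <- Ut[, cols, drop = FALSE]
    Y <- Matrix::solve(Ch, Matrix::solve(Ch, B, system = "P"), system = "L")
    tr_a <- tr_a + sum(Y^2)
  }
  tr_pe <- 0
  for (start in seq(1L, ws$qpe, by = chunk)) {
    cols <- start:min(start + chunk - 1L, ws$qpe)
    B <- Matrix::sparseMatrix(i = ws$ix_pe[cols], j = seq_along(cols), x = 1,
                              dims = c(ntot, length(cols)))
    Y <- Matrix::solve(Ch, Matrix::solve(Ch, B, system = "P"), system = "L")
    tr_pe <- tr_pe + sum(Y^2)
  }
  list(tr_a = tr_a, tr_pe = tr_pe)
}

# Score vector for (sigma2_a, sigma2_pe, sigma2_e).
reml_gradient <- function(ws, vc, sol, traces) {
  ahat <- sol[ws$ix_a]
  pehat <- sol[ws$ix_pe]
  ehat <- ws$y - as.numeric(ws$W %*% sol)
  aAa <- sum(ahat * as.numeric(ws$Ainv %*% ahat))
  pp <- sum(pehat^2)
  ee <- sum(ehat^2)
  dim_tot <- ws$p + ws$qa + ws$qpe
  g_a <- -0.5 * (ws$qa / vc$sigma2_a - traces$tr_a / vc$sigma2_a^2 -
                   aAa / vc$sigma2_a^2)
  g_pe <- -0.5 * (ws$qpe / vc$sigma2_pe - traces$tr_pe / vc$sigma2_pe^2 -
                    pp / vc$sigma2_pe^2)
  trP <- (ws$n - dim_tot + traces$tr_a / vc$sigma2_a +
            traces$tr_pe / vc$sigma2_pe) / vc$sigma2_e
  g_e <- -0.5 * (trP - ee / vc$sigma2_e^2)
  list(grad = c(g_a, g_pe, g_e), ahat = ahat, pehat = pehat, ehat = ehat,
       aAa = aAa, pp = pp, ee = ee)
}

# Average-information matrix from the working vectors.
reml_ai_matrix <- function(ws, vc, Ch, parts) {
  Fmat <- cbind(
    as.numeric(ws$W[, ws$ix_a] %*% parts$ahat) / vc$sigma2_a,
    as.numeric(ws$W[, ws$ix_pe] %*% parts$pehat) / vc$sigma2_pe,
    parts$ehat / vc$sigma2_e
  )
  WtF <- as.matrix(Matrix::crossprod(ws$W, Fmat)) / vc$sigma2_e
  solF <- as.matrix(Matrix::solve(Ch, WtF))
  PF <- (Fmat - as.matrix(ws$W %*% solF)) / vc$sigma2_e
  0.5 * crossprod(Fmat, PF)
}

#' Estimate variance components by AI-REML
#'
#' Maximizes the restricted likelihood of the pedigree repeatability model by
#' average-information REML with EM fallback steps whenever an AI update
#' leaves the parameter space or decreases the restricted likelihood.
#' Convergence is declared when the largest relative parameter change drops
#' below `tol` (default 1e-8), with at most `max_iter` iterations; on
#' non-convergence the best iterate is returned with `converged = FALSE`.
#'
#' @param ped Pedigree tibble (topological order).
#' @param records Trait records tibble (`animal`, `parity`, `hys`, `value`).
#' @param init Optional starting `varcomp`; defaults to an even split of the
#'   phenotypic variance (50% residual, 30% additive, 20% permanent).
#' @param max_iter,tol Iteration limit and relative-change tolerance.
#' @param verbose Print per-iteration progress.
#' @return A `varcomp` with heritability standard error from the inverse AI
#'   matrix (delta method).
#' @export
estimate_reml <- function(ped, records, init = NULL, max_iter = 200L,
                          tol = 1e-8, verbose = FALSE) {
  ws <- repeatability_design(ped, records)
  if (length(ws$hys_levels) < 2L) {
    warn("fewer than two herd-year-season levels; fixed effects barely identified")
  }
  if (!any(duplicated(records$animal))) {
    warn("no repeated records; permanent-environment variance is weakly identified")
  }
  vy <- var(ws$y)
  floor_v <- 1e-6 * vy
  vc <- init %||% variance_components(0.3 * vy, 0.2 * vy, 0.5 * vy)
  theta <- pmax(c(vc$sigma2_a, vc$sigma2_pe, vc$sigma2_e), floor_v)
  Ch <- NULL
  pieces <- NULL
  make_vc <- function(th) variance_components(th[1], th[2], th[3])
  cur <- make_vc(theta)
  pieces <- reml_loglik_pieces(ws, cur, Ch)
  Ch <- pieces$Ch
  ll <- pieces$loglik
  n_iter <- 0L
  converged <- FALSE
  ai <- NULL
  for (it in seq_len(max_iter)) {
    n_iter <- it
    traces <- mme_traces(ws, Ch)
    gparts <- reml_gradient(ws, cur, pieces$sol, traces)
    ai <- reml_ai_matrix(ws, cur, Ch, gparts)
    # active set: components at the boundary stay fixed unless their
    # gradient points back into the interior
    free <- theta > 10 * floor_v | gparts$grad > 0
    step <- rep(0, 3)
    step_free <- tryCatch(solve(ai[free, free, drop = FALSE], gparts$grad[free]),
                          error = function(e) NULL)
    if (!is.null(step_free)) step[free] <- step_free else step <- NULL
    accepted <- FALSE
    if (!is.null(step) && all(is.finite(step)) && any(step != 0)) {
      # damped AI steps, components clamped at the parameter-space floor
      for (s in c(1, 0.5, 0.25, 0.1)) {
        proposal <- pmax(theta + s * step, floor_v)
        cand <- make_vc(proposal)
        cand_pieces <- tryCatch(reml_loglik_pieces(ws, cand, Ch),
                                error = function(e) NULL)
        if (!is.null(cand_pieces) && is.finite(cand_pieces$loglik) &&
            cand_pieces$loglik >= ll - 1e-10) {
          accepted <- TRUE
          new_theta <- proposal
          pieces <- cand_pieces; Ch <- pieces$Ch
          break
        }
      }
    }
    if (!accepted) {
      # EM fallback: guaranteed-ascent expectation-maximization update
      dim_tot <- ws$p + ws$qa + ws$qpe
      em <- c(
        (gparts$aAa + traces$tr_a) / ws$qa,
        (gparts$pp + traces$tr_pe) / ws$qpe,
        (gparts$ee + cur$sigma2_e *
           (dim_tot - traces$tr_a / cur$sigma2_a - traces$tr_pe / cur$sigma2_pe)) / ws$n
      )
      new_theta <- pmax(em, floor_v)
      cand <- make_vc(new_theta)
      pieces <- reml_loglik_pieces(ws, cand, Ch)
      Ch <- pieces$Ch
    }
    rel <- max(abs(new_theta - theta) / (abs(theta) + 1e-12))
    theta <- new_theta
    cur <- make_vc(theta)
    ll <- pieces$loglik
    if (verbose) {
      message(sprintf("iter %3d  logL %.6f  s2a %.5f s2pe %.5f s2e %.5f (%s)",
                      it, ll, theta[1], theta[2], theta[3],
                      if (accepted) "AI" else "EM"))
    }
    if (rel < tol) { converged <- TRUE; break }
  }
  se_h2 <- NA_real_
  if (!is.null(ai)) {
    tot <- sum(theta)
    dh <- c((tot - theta[1]) / tot^2, -theta[1] / tot^2, -theta[1] / tot^2)
    V <- tryCatch(solve(ai), error = function(e) NULL)
    if (!is.null(V)) se_h2 <- sqrt(max(drop(t(dh) %*% V %*% dh), 0))
  }
  variance_components(theta[1], theta[2], theta[3], se_h2 = se_h2,
                      converged = converged, n_iter = n_iter, loglik = ll)
}

#' Solve the mixed model equations of the repeatability model
#'
#' Henderson's MME with `A^-1 sigma2_e / sigma2_a` and
#' `I sigma2_e / sigma2_pe` penalties. Every pedigree animal receives an EBV
#' (recordless animals through their relatives); residuals are per record.
#'
#' @param ped Pedigree tibble.
#' @param records Trait records tibble.
#' @param vc A `varcomp` (e.g. from [estimate_reml()]); `sigma2_e` must be
#'   strictly positive.
#' @return A `blup_solution`: list with `fixed_effects`, `ebv`, `pe_hat`,
#'   `residuals` tibbles and the `vc` used.
#' @export
solve_mme <- function(ped, records, vc) {
  stopifnot(inherits(vc, "varcomp"))
  if (vc$sigma2_e <= 0) abort("`sigma2_e` must be strictly positive")
  ws <- repeatability_design(ped, records)
  vc_use <- variance_components(max(vc$sigma2_a, vc$sigma2_e * 1e-12),
                                max(vc$sigma2_pe, vc$sigma2_e * 1e-12),
                                vc$sigma2_e)
  pieces <- reml_loglik_pieces(ws, vc_use)
  sol <- pieces$sol
  fitted <- as.numeric(ws$W %*% sol)
  structure(
    list(
      fixed_effects = tibble::tibble(hys = ws$hys_levels,
                                     estimate = sol[ws$ix_f]),
      ebv = tibble::tibble(animal = ws$animals, ebv = sol[ws$ix_a]),
      pe_hat = tibble::tibble(animal = ws$pe_ids, pe_hat = sol[ws$ix_pe]),
      residuals = dplyr::mutate(ws$records, fitted = fitted,
                                residual = .data$value - fitted),
      vc = vc
    ),
    class = "blup_solution"
  )
}

#' @export
print.blup_solution <- function(x, ...) {
  cat(sprintf("<blup_solution> %d animals, %d records, %d fixed levels\n",
              nrow(x$ebv), nrow(x$residuals), nrow(x$fixed_effects)))
  invisible(x)
}

#' Corrected phenotypes
#'
#' `y_c(i) = EBV(i) + mean(residuals of i's own records)`; animals without
#' records receive `y_c = EBV` and are flagged, so that reference sets can
#' exclude them.
#'
#' @param sol A `blup_solution` from [solve_mme()].
#' @return Tibble with `animal`, `y_c`, `n_records`, `has_records`.
#' @export
corrected_phenotypes <- function(sol) {
  stopifnot(inherits(sol, "blup_solution"))
  resid_mean <- sol$residuals |>
    dplyr::group_by(.data$animal) |>
    dplyr::summarise(mean_resid = mean(.data$residual),
                     n_records = dplyr::n(), .groups = "drop")
  sol$ebv |>
    dplyr::left_join(resid_mean, by = "animal") |>
    dplyr::mutate(
      n_records = dplyr::coalesce(.data$n_records, 0L),
      has_records = .data$n_records > 0L,
      y_c = .data$ebv + dplyr::coalesce(.data$mean_resid, 0)
    ) |>
    dplyr::select("animal", "y_c", "n_records", "has_records")
}
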