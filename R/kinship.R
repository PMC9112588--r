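# Relationship matrices: pedigree A and its sparse inverse, the VanRaden
# genomic relationship matrix G, the blended G_w and the single-step H-inverse.

#' Numerator relationship matrix (tabular method)
#'
#' Builds the pedigree relationship matrix A by the tabular recursion,
#' including inbreeding. The pedigree must be in topological order (parents
#' before offspring); readers and the simulator guarantee this.
#'
#' @param ped Pedigree tibble with columns `animal`, `sire`, `dam`.
#' @return Dense symmetric matrix with animal ids as dimnames.
#' @export
build_A <- function(ped) {
  pidx <- parent_index(ped)
  A <- .tabular_A(pidx$sire, pidx$dam)
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Pedigree inbreeding coefficients
#'
#' Meuwissen & Luo style recursion over the ancestor list of each animal.
#'
#' @param ped Pedigree tibble in topological order.
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  pidx <- parent_index(ped)
  setNames(.inbreeding_ml(pidx$sire, pidx$dam), ped$animal)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes 1/d_i to its
#' diagonal and the usual -1/2d_i, 1/4d_i terms to parent entries, where d_i
#' is the Mendelian sampling variance computed from parental inbreeding.
#'
#' @param ped Pedigree tibble in topological order.
#' @return Sparse symmetric `Matrix` with attribute `logdet` (log det A).
#' @export
build_A_inverse <- function(ped) {
  pidx <- parent_index(ped)
  f <- .inbreeding_ml(pidx$sire, pidx$dam)
  n <- nrow(ped)
  s <- pidx$sire; d <- pidx$dam
  fs <- ifelse(s > 0L, f[pmax(s, 1L)], 0)
  fd <- ifelse(d > 0L, f[pmax(d, 1L)], 0)
  dmend <- ifelse(s > 0L & d > 0L, 0.5 - 0.25 * (fs + fd),
           ifelse(s > 0L | d > 0L, 0.75 - 0.25 * (fs + fd), 1))
  alpha <- 1 / dmend
  ii <- list(); jj <- list(); xx <- list()
  add <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  idx <- seq_len(n)
  add(idx, idx, alpha)
  both <- which(s > 0L & d > 0L)
  if (length(both)) {
    add(both, s[both], -0.5 * alpha[both]); add(s[both], both, -0.5 * alpha[both])
    add(both, d[both], -0.5 * alpha[both]); add(d[both], both, -0.5 * alpha[both])
    add(s[both], s[both], 0.25 * alpha[both])
    add(d[both], d[both], 0.25 * alpha[both])
    add(s[both], d[both], 0.25 * alpha[both]); add(d[both], s[both], 0.25 * alpha[both])
  }
  one <- which(xor(s > 0L, d > 0L))
  if (length(one)) {
    pp <- pmax(s[one], d[one])
    add(one, pp, -0.5 * alpha[one]); add(pp, one, -0.5 * alpha[one])
    add(pp, pp, 0.25 * alpha[one])
  }
  Ai <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx), dims = c(n, n),
    dimnames = list(ped$animal, ped$animal), symmetric = FALSE
  )
  Ai <- Matrix::forceSymmetric((Ai + Matrix::t(Ai)) / 2)
  attr(Ai, "logdet") <- sum(log(dmend))
  Ai
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = M M' / (2 * sum_j p_j (1 - p_j))` with `M` the dosage matrix centered
#' by twice the observed allele frequencies. Frequencies are computed on the
#' supplied animals (the full genotyped set; G is built once per dataset).
#'
#' @param geno A `geno_matrix` or a complete dosage matrix with dimnames.
#' @return Dense symmetric matrix over the genotyped animals, with the
#'   centering frequencies in attribute `allele_freq` and the scaling constant
#'   in attribute `denom`.
#' @export
build_G <- function(geno) {
  dos <- if (inherits(geno, "geno_matrix")) geno$dosage else geno
  if (anyNA(dos)) abort("G requires complete dosages; run QC/imputation first")
  p <- colMeans(dos) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) abort("all markers are monomorphic; G denominator is zero")
  M <- sweep(dos, 2L, 2 * p, "-")
  G <- tcrossprod(M) / denom
  dimnames(G) <- list(rownames(dos), rownames(dos))
  attr(G, "allele_freq") <- p
  attr(G, "denom") <- denom
  G
}

#' Blend G with the pedigree relationship block
#'
#' `G_w = (1 - w) G + w A22`, the standard remedy against a singular genomic
#' relationship matrix; the default weight is `w = 0.05`.
#'
#' @param G Genomic relationship matrix.
#' @param A22 Pedigree relationship block of the genotyped animals, in the
#'   same id order as `G`.
#' @param w Blending weight in \[0, 1\].
#' @return Blended matrix `G_w`.
#' @export
blend_G <- function(G, A22, w = 0.05) {
  check_square_named(G, "G"); check_square_named(A22, "A22")
  assert_scalar_num(w, "w", 0, 1)
  if (!identical(rownames(G), rownames(A22))) {
    abort("`G` and `A22` must share the same animal ids in the same order")
  }
  Gw <- (1 - w) * G + w * as.matrix(A22)
  dimnames(Gw) <- dimnames(G)
  Gw
}

#' Single-step H-inverse
#'
#' Assembles the inverse of the combined pedigree-genomic relationship matrix:
#' `H^-1 = A^-1 + [[Gw^-1 - A22^-1, 0], [0, 0]]`, the genotyped-block
#' correction added to the sparse pedigree inverse, ordered as `A_inv`.
#'
#' @param A_inv Sparse pedigree inverse over all animals ([build_A_inverse()]).
#' @param Gw_inv Inverse of the blended genomic matrix (genotyped animals).
#' @param A22_inv Inverse of the pedigree block of the genotyped animals.
#' @param genotyped_ids Character ids of the genotyped animals (must index
#'   `Gw_inv`/`A22_inv` rows in order and be a subset of `A_inv` ids).
#' @return Sparse symmetric matrix `H^-1` with ids of `A_inv`.
#' @export
build_H_inverse <- function(A_inv, Gw_inv, A22_inv, genotyped_ids) {
  ids <- rownames(A_inv)
  if (!all(genotyped_ids %in% ids)) {
    abort("some genotyped ids are absent from the pedigree")
  }
  if (length(genotyped_ids) &&
      (!identical(rownames(Gw_inv), genotyped_ids) ||
       !identical(rownames(A22_inv), genotyped_ids))) {
    abort("`Gw_inv` and `A22_inv` must be indexed by `genotyped_ids` in order")
  }
  H <- methods::as(A_inv, "CsparseMatrix")
  if (length(genotyped_ids)) {
    pos <- match(genotyped_ids, ids)
    corr <- as.matrix(Gw_inv) - as.matrix(A22_inv)
    extra <- Matrix::sparseMatrix(
      i = rep(pos, times = length(pos)), j = rep(pos, each = length(pos)),
      x = as.numeric(t(corr)), dims = dim(H), dimnames = dimnames(H)
    )
    H <- H + extra
  }
  Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
}

#' Convenience constructor for the single-step matrices
#'
#' Builds A22 from the pedigree, blends G, inverts the two genotyped blocks
#' and assembles the H-inverse. Inversion of the blended matrix is by dense
#' Cholesky; a non-positive-definite `G_w` is an error (increase `w`).
#'
#' @param ped Pedigree tibble.
#' @param G Genomic relationship matrix over the genotyped animals.
#' @param w Blending weight passed to [blend_G()].
#' @return List with `H_inv`, `Gw`, `A22` and `A_inv`.
#' @export
single_step_matrices <- function(ped, G, w = 0.05) {
  ids <- rownames(G)
  A <- build_A(ped)
  if (!all(ids %in% rownames(A))) abort("genotyped animals missing from pedigree")
  A22 <- A[ids, ids, drop = FALSE]
  Gw <- blend_G(G, A22, w)
  ch <- tryCatch(chol(Gw), error = function(e) {
    abort("blended G_w is not positive definite; increase the blending weight w")
  })
  Gw_inv <- chol2inv(ch)
  dimnames(Gw_inv) <- dimnames(Gw)
  A22_inv <- solve(A22)
  dimnames(A22_inv) <- dimnames(A22)
  A_inv <- build_A_inverse(ped)
  list(
    H_inv = build_H_inverse(A_inv, Gw_inv, A22_inv, ids),
    Gw = Gw, A22 = A22, A_inv = A_inv
  )
}
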