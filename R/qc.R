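# Genotype quality control and imputation-concordance metrics.

#' SNP and individual quality control
#'
#' Applies the three filters in order: (1) markers with minor allele
#' frequency below `maf_min`, (2) markers with call rate below
#' `marker_callrate`, (3) individuals with call rate below
#' `animal_callrate`. MAF is computed on non-missing calls.
#'
#' @param geno A `geno_matrix`.
#' @param maf_min MAF threshold (markers strictly below are removed).
#' @param marker_callrate,animal_callrate Call-rate thresholds (strictly
#'   below removed).
#' @return List with `genotypes` (filtered `geno_matrix`) and `report`
#'   (tibble of removal counts per rule).
#' @export
qc_filter <- function(geno, maf_min = 0.01, marker_callrate = 0.90,
                      animal_callrate = 0.90) {
  stopifnot(inherits(geno, "geno_matrix"))
  dos <- geno$dosage
  p_hat <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  maf[is.nan(maf)] <- 0
  drop_maf <- maf < maf_min
  cr_marker <- colMeans(!is.na(dos))
  drop_cr <- !drop_maf & cr_marker < marker_callrate
  keep_markers <- !(drop_maf | drop_cr)
  dos2 <- dos[, keep_markers, drop = FALSE]
  cr_animal <- rowMeans(!is.na(dos2))
  drop_animal <- cr_animal < animal_callrate
  dos3 <- dos2[!drop_animal, , drop = FALSE]
  if (ncol(dos3) == 0L) abort("quality control removed every marker")
  report <- tibble::tibble(
    rule = c("marker_maf", "marker_callrate", "animal_callrate"),
    threshold = c(maf_min, marker_callrate, animal_callrate),
    removed = c(sum(drop_maf), sum(drop_cr), sum(drop_animal))
  )
  list(
    genotypes = geno_matrix(dos3,
                            map = geno$map[keep_markers, , drop = FALSE],
                            founder_freq = geno$founder_freq[keep_markers]),
    report = report
  )
}

#' Imputation concordance metrics
#'
#' Compares imputed against true genotypes on their shared animals and
#' markers: the genotype concordance rate CR (fraction of exactly matching
#' non-missing calls) and the genotype correlation COR (Pearson correlation
#' of dosages), overall and stratified by MAF bin and chromosome. Per-marker
#' values are averaged within strata; the overall row pools all calls.
#'
#' @param imputed,truth `geno_matrix` objects sharing animals and markers.
#' @param maf_bins Breakpoints of the MAF strata (computed on `truth`).
#' @param by_chrom Also stratify by chromosome.
#' @return List of tibbles: `overall`, `by_maf`, and `by_chrom` (if
#'   requested).
#' @export
concordance <- function(imputed, truth, maf_bins = seq(0, 0.5, by = 0.05),
                        by_chrom = TRUE) {
  stopifnot(inherits(imputed, "geno_matrix"), inherits(truth, "geno_matrix"))
  ids <- intersect(rownames(imputed$dosage), rownames(truth$dosage))
  mks <- intersect(colnames(imputed$dosage), colnames(truth$dosage))
  if (!length(ids) || !length(mks)) abort("no shared animals/markers to compare")
  A <- imputed$dosage[ids, mks, drop = FALSE]
  B <- truth$dosage[ids, mks, drop = FALSE]
  ok <- !is.na(A) & !is.na(B)
  per_marker <- tibble::tibble(
    marker = mks,
    cr = vapply(seq_along(mks), function(j) {
      k <- ok[, j]
      if (!any(k)) return(NA_real_)
      mean(A[k, j] == B[k, j])
    }, numeric(1)),
    cor = vapply(seq_along(mks), function(j) {
      k <- ok[, j]
      if (sum(k) < 2L || sd(B[k, j]) == 0 || sd(A[k, j]) == 0) return(NA_real_)
      cor(A[k, j], B[k, j])
    }, numeric(1))
  )
  p_hat <- colMeans(B, na.rm = TRUE) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  per_marker$maf_bin <- cut(maf, breaks = maf_bins, include.lowest = TRUE)
  chrom <- truth$map$chrom[match(mks, truth$map$marker)]
  per_marker$chrom <- chrom
  overall <- tibble::tibble(
    n_calls = sum(ok),
    cr = mean(A[ok] == B[ok]),
    cor = if (sd(B[ok]) > 0 && sd(A[ok]) > 0) cor(A[ok], B[ok]) else NA_real_
  )
  by_maf <- per_marker |>
    dplyr::group_by(.data$maf_bin) |>
    dplyr::summarise(n_markers = dplyr::n(),
                     cr = mean(.data$cr, na.rm = TRUE),
                     cor = mean(.data$cor, na.rm = TRUE), .groups = "drop")
  out <- list(overall = overall, by_maf = by_maf, per_marker = per_marker)
  if (by_chrom) {
    out$by_chrom <- per_marker |>
      dplyr::group_by(chrom = .data$chrom) |>
      dplyr::summarise(n_markers = dplyr::n(),
                       cr = mean(.data$cr, na.rm = TRUE),
                       cor = mean(.data$cor, na.rm = TRUE), .groups = "drop")
  }
  out
}
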