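# File interchange: genotypes (VCF, dosage TSV, plink .raw), pedigree and
# phenotype CSV, metric TSV and run manifests. Readers validate and reject
# malformed input rather than silently coercing.

#' Read genotypes
#'
#' Supported formats: `"vcf"` (GT field summed to dosage; any half-missing
#' call such as `./1` becomes missing), `"dosage"` (TSV, first column animal
#' id, remaining columns marker dosages 0/1/2 or NA) and `"plink_raw"`
#' (output of `plink --recode A`). Format is guessed from the file extension
#' when `"auto"`.
#'
#' @param path Input file.
#' @param format One of `"auto"`, `"vcf"`, `"dosage"`, `"plink_raw"`.
#' @return A `geno_matrix`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage", "plink_raw")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
    else if (grepl("\\.raw$", path)) "plink_raw"
    else "dosage"
  }
  switch(format,
    vcf = read_vcf_genotypes(path),
    dosage = read_dosage_tsv(path),
    plink_raw = read_plink_raw(path)
  )
}

read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0L) abort("no GT genotypes found in VCF")
  dose_one <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)   # half-missing -> missing
    suppressWarnings(al <- as.integer(alleles))
    if (anyNA(al)) abort(sprintf("malformed GT entry `%s`", g))
    sum(al > 0L)
  }
  dos <- t(apply(gt, c(1, 2), dose_one))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  marker <- ifelse(is.na(fix$ID) | fix$ID == ".",
                   paste0(fix$CHROM, "_", fix$POS), fix$ID)
  if (anyDuplicated(marker)) abort("duplicated marker ids in VCF")
  if (anyDuplicated(rownames(dos))) abort("duplicated sample ids in VCF")
  colnames(dos) <- marker
  dos <- matrix(as.integer(dos), nrow = nrow(dos), dimnames = dimnames(dos))
  geno_matrix(dos, map = tibble::tibble(marker = marker,
                                        chrom = fix$CHROM,
                                        pos = as.integer(fix$POS)))
}

read_dosage_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2L) abort("dosage TSV needs an id column and >= 1 marker")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) abort("duplicated animal ids in dosage TSV")
  dos <- as.matrix(tab[, -1L, drop = FALSE])
  bad <- dos[!is.na(dos)]
  if (length(bad) && !all(bad %in% 0:2)) {
    abort("dosage TSV entries must be 0, 1, 2 or missing")
  }
  storage.mode(dos) <- "integer"
  rownames(dos) <- ids
  geno_matrix(dos)
}

read_plink_raw <- function(path) {
  tab <- readr::read_table(path, show_col_types = FALSE, progress = FALSE)
  need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(need %in% names(tab))) abort("not a plink --recode A file")
  ids <- as.character(tab$IID)
  if (anyDuplicated(ids)) abort("duplicated IID in plink raw file")
  dos <- as.matrix(tab[, setdiff(names(tab), need), drop = FALSE])
  storage.mode(dos) <- "integer"
  rownames(dos) <- ids
  colnames(dos) <- sub("_[ACGT0-9]+$", "", colnames(dos))
  geno_matrix(dos)
}

#' Write genotypes as dosage TSV
#'
#' @param geno A `geno_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "geno_matrix"))
  tab <- tibble::as_tibble(geno$dosage, rownames = "animal")
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a pedigree CSV
#'
#' Expected header: `animal,sire,dam,sex,birth_date` (unknown parents coded
#' `"0"` or empty). Rows are re-ordered topologically; a cyclic pedigree is
#' an error naming the animals on the cycle.
#'
#' @param path Input CSV.
#' @return Pedigree tibble in topological order.
#' @export
read_pedigree <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(tab))) {
    abort("pedigree CSV needs columns animal, sire, dam")
  }
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "0", "NA")] <- NA_character_
    x
  }
  ped <- tibble::tibble(
    animal = as.character(tab$animal),
    sire = clean(tab$sire),
    dam = clean(tab$dam),
    sex = if ("sex" %in% names(tab)) as.character(tab$sex) else NA_character_,
    birth_date = if ("birth_date" %in% names(tab)) as.Date(tab$birth_date) else as.Date(NA)
  )
  if (anyDuplicated(ped$animal)) abort("duplicated animal ids in pedigree")
  unknown <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$animal)
  if (length(unknown)) {
    abort(sprintf("parents missing from pedigree: %s",
                  paste(head(unknown, 5L), collapse = ", ")))
  }
  topo_sort_pedigree(ped)
}

# Kahn topological sort; errors with the cycle membership if one exists.
topo_sort_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal)
  parents <- cbind(idx[ped$sire], idx[ped$dam])
  indeg <- rowSums(!is.na(parents))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in parents[i, ]) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    cyc <- ped$animal[setdiff(seq_len(n), order)]
    abort(sprintf("pedigree contains a cycle involving: %s",
                  paste(head(cyc, 10L), collapse = ", ")))
  }
  ped[order, , drop = FALSE]
}

#' Read trait records CSV
#'
#' Expected header: `animal,parity,hys,value`. When a pedigree is supplied,
#' records of unknown animals are an error listing the offending ids.
#'
#' @param path Input CSV.
#' @param pedigree Optional pedigree tibble for id validation.
#' @return Records tibble.
#' @export
read_phenotypes <- function(path, pedigree = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("animal", "parity", "hys", "value")
  if (!all(need %in% names(tab))) {
    abort("phenotype CSV needs columns animal, parity, hys, value")
  }
  rec <- tibble::tibble(
    animal = as.character(tab$animal),
    parity = as.integer(tab$parity),
    hys = factor(tab$hys),
    value = as.numeric(tab$value)
  )
  if (anyNA(rec$value)) abort("missing phenotype values")
  if (!is.null(pedigree)) {
    orphan <- setdiff(unique(rec$animal), pedigree$animal)
    if (length(orphan)) {
      abort(sprintf("phenotypes for unknown animals: %s",
                    paste(orphan, collapse = ", ")))
    }
  }
  rec
}

#' Write a pedigree / records CSV
#'
#' @param x Pedigree or records tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @name write_tables
NULL

#' @rdname write_tables
#' @export
write_pedigree <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_tables
#' @export
write_phenotypes <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record sufficient to reproduce a benchmark run: configuration,
#' seeds, fold-plan hash and input hashes.
#'
#' @param path Output JSON path.
#' @param config Named list of run settings.
#' @param plan_hash Fold-plan hash (from a `cv_plan` or `benchmark_result`).
#' @param inputs Optional named list of file paths to hash.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, plan_hash = NULL, inputs = NULL) {
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    config_hash = rlang::hash(config),
    plan_hash = plan_hash,
    input_hashes = if (!is.null(inputs)) {
      lapply(inputs, function(f) rlang::hash(readBin(f, "raw", file.size(f))))
    }
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
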