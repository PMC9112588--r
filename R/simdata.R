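# Simulation of breeding populations: pedigree, SNP genotypes (gene dropping),
# and repeated litter-size phenotypes under a repeatability model.

#' Simulation configuration
#'
#' Parameters of the synthetic breeding population. The variance-component
#' defaults correspond to total number born (TNB) in a Yorkshire sow herd:
#' additive variance 1.26, residual variance 8.95 and permanent-environment
#' variance 0.29, which together give heritability
#' `1.26 / (1.26 + 0.29 + 8.95) = 0.12` and repeatability 0.148.
#'
#' The default desk-scale population (100 founders, 3 generations, 3 offspring
#' per mating) has about 800 animals; a study-scale population of roughly
#' 4,000 animals with ~2,000 sows is obtained with
#' `sim_config(n_founders = 500, n_generations = 3, offspring_per_mating = 3)`.
#'
#' @param n_founders Number of founder animals (split evenly between sexes).
#' @param n_generations Number of descendant generations to breed.
#' @param offspring_per_mating Litter size of the simulated matings.
#' @param n_markers Number of biallelic SNP markers (unlinked).
#' @param maf_range Range (min, max) of founder minor allele frequencies,
#'   within (0, 0.5].
#' @param sigma2_a Additive genetic variance (trait units squared).
#' @param sigma2_pe Permanent-environment variance of sows.
#' @param sigma2_e Residual variance.
#' @param n_qtl Number of markers carrying QTL effects (a random subset of the
#'   panel; QTL stay in the panel).
#' @param records_per_sow Integer vector of admissible record counts per sow;
#'   each sow draws her parity count uniformly from it.
#' @param n_hys_levels Number of herd-year-season levels.
#' @param hys_effect_sd Standard deviation of the herd-year-season fixed
#'   effects (trait units).
#' @param genotyped_fraction Fraction of animals flagged as genotyped.
#' @param seed Master seed; per-stage child seeds are derived from it.
#'
#' @return A `sim_config` object (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_founders = 10, n_generations = 1, n_markers = 50)
sim_config <- function(n_founders = 100L,
                       n_generations = 3L,
                       offspring_per_mating = 3L,
                       n_markers = 2000L,
                       maf_range = c(0.05, 0.5),
                       sigma2_a = 1.26,
                       sigma2_pe = 0.29,
                       sigma2_e = 8.95,
                       n_qtl = 100L,
                       records_per_sow = 1:3,
                       n_hys_levels = 8L,
                       hys_effect_sd = 1,
                       genotyped_fraction = 0.66,
                       seed = 1L) {
  n_founders <- assert_count(n_founders, "n_founders", min = 2L)
  n_generations <- assert_count(n_generations, "n_generations", min = 0L)
  offspring_per_mating <- assert_count(offspring_per_mating, "offspring_per_mating", min = 1L)
  n_markers <- assert_count(n_markers, "n_markers", min = 1L)
  n_qtl <- assert_count(n_qtl, "n_qtl", min = 0L)
  assert_scalar_num(sigma2_a, "sigma2_a", lower = 0)
  assert_scalar_num(sigma2_pe, "sigma2_pe", lower = 0)
  assert_scalar_num(sigma2_e, "sigma2_e", lower = 0)
  assert_scalar_num(genotyped_fraction, "genotyped_fraction", lower = 0, upper = 1)
  assert_scalar_num(hys_effect_sd, "hys_effect_sd", lower = 0)
  n_hys_levels <- assert_count(n_hys_levels, "n_hys_levels", min = 1L)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair within (0, 0.5]")
  }
  if (n_qtl > n_markers) abort("`n_qtl` cannot exceed `n_markers`")
  if (!is.numeric(records_per_sow) || length(records_per_sow) < 1L ||
      any(records_per_sow < 1) || any(records_per_sow != floor(records_per_sow))) {
    abort("`records_per_sow` must be positive integers")
  }
  tot <- sigma2_a + sigma2_pe + sigma2_e
  h2 <- if (tot > 0) sigma2_a / tot else 0
  if (h2 < 0 || h2 >= 1) abort("implied heritability must lie in [0, 1)")
  structure(
    list(
      n_founders = n_founders, n_generations = n_generations,
      offspring_per_mating = offspring_per_mating, n_markers = n_markers,
      maf_range = as.numeric(maf_range), sigma2_a = sigma2_a,
      sigma2_pe = sigma2_pe, sigma2_e = sigma2_e, n_qtl = n_qtl,
      records_per_sow = as.integer(records_per_sow),
      n_hys_levels = n_hys_levels, hys_effect_sd = hys_effect_sd,
      genotyped_fraction = genotyped_fraction, seed = as.integer(seed),
      h2 = h2
    ),
    class = "sim_config"
  )
}

#' Study-scale simulation preset
#'
#' Configuration emulating the benchmark's source population: roughly 4,000
#' pedigree animals with about 2,000 sows carrying two litter-size records
#' each across 20 herd-year-season levels, at the published variance
#' components (sigma2_a = 1.26, sigma2_pe = 0.29, sigma2_e = 8.95; h2 = 0.12).
#' The marker panel is kept at 1,000 markers with 300 QTL: variance-component
#' work only needs the polygenic signal, and a panel of that size keeps the
#' genetic architecture realistically polygenic for a litter-size trait.
#'
#' @param seed Master seed.
#' @return A [sim_config()].
#' @export
study_config <- function(seed = 1L) {
  sim_config(n_founders = 500L, n_generations = 3L, offspring_per_mating = 3L,
             n_markers = 1000L, n_qtl = 300L, records_per_sow = 2L,
             n_hys_levels = 20L, seed = seed)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  population: %d founders, %d generations, %d offspring/mating\n",
              x$n_founders, x$n_generations, x$offspring_per_mating))
  cat(sprintf("  markers: %d (%d QTL), founder MAF in [%.2f, %.2f]\n",
              x$n_markers, x$n_qtl, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  variances: sigma2_a=%.3g sigma2_pe=%.3g sigma2_e=%.3g (h2=%.3f)\n",
              x$sigma2_a, x$sigma2_pe, x$sigma2_e, x$h2))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Simulate a generational pedigree
#'
#' Founders form generation 0 with alternating sexes and unknown parents.
#' In each later generation every female of the previous generation is mated
#' to a randomly drawn male of that generation, producing
#' `offspring_per_mating` offspring of random sex. Birth dates advance by one
#' calendar year per generation (with a random day within the year), so a
#' forward split by date is always possible when `n_generations >= 1`.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `animal`, `sire`, `dam` (NA for unknown),
#'   `sex` ("male"/"female"), `birth_date` (Date) and `generation`, in
#'   topological order (parents precede offspring).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_founders < 2L) abort("need at least two founders")
  with_seed(derive_seed(cfg$seed, "pedigree"), {
    sex0 <- rep(c("male", "female"), length.out = cfg$n_founders)
    rows <- list(tibble::tibble(
      idx = seq_len(cfg$n_founders), sire = NA_integer_, dam = NA_integer_,
      sex = sex0, generation = 0L
    ))
    prev <- rows[[1L]]
    n_total <- cfg$n_founders
    for (g in seq_len(cfg$n_generations)) {
      dams <- prev$idx[prev$sex == "female"]
      sires <- prev$idx[prev$sex == "male"]
      if (length(dams) == 0L || length(sires) == 0L) {
        abort(sprintf("generation %d has a single sex; no matings possible", g - 1L))
      }
      sire_of <- sample(sires, length(dams), replace = TRUE)
      n_off <- length(dams) * cfg$offspring_per_mating
      off <- tibble::tibble(
        idx = n_total + seq_len(n_off),
        sire = rep(sire_of, each = cfg$offspring_per_mating),
        dam = rep(dams, each = cfg$offspring_per_mating),
        sex = sample(c("male", "female"), n_off, replace = TRUE),
        generation = g
      )
      n_total <- n_total + n_off
      rows[[g + 1L]] <- off
      prev <- off
    }
    ped <- dplyr::bind_rows(rows)
    id_of <- sprintf("A%05d", ped$idx)
    ped$birth_date <- as.Date(sprintf("%04d-01-01", 2016L + ped$generation)) +
      sample.int(330L, nrow(ped), replace = TRUE)
    tibble::tibble(
      animal = id_of,
      sire = ifelse(is.na(ped$sire), NA_character_, id_of[ped$sire]),
      dam = ifelse(is.na(ped$dam), NA_character_, id_of[ped$dam]),
      sex = ped$sex,
      birth_date = ped$birth_date,
      generation = ped$generation
    )
  })
}

# Integer parent indices (0 = unknown) for a topologically ordered pedigree.
parent_index <- function(ped) {
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$animal
  s <- idx[ped$sire]
  d <- idx[ped$dam]
  s[is.na(s)] <- 0L
  d[is.na(d)] <- 0L
  bad <- which(s >= idx & s > 0L | d >= idx & d > 0L)
  if (length(bad)) {
    abort(sprintf("pedigree is not topologically ordered at animal %s",
                  ped$animal[bad[1]]))
  }
  list(sire = unname(as.integer(s)), dam = unname(as.integer(d)))
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founder allele frequencies are drawn uniformly within `cfg$maf_range`;
#' founder haplotypes are Bernoulli draws, and every non-founder inherits one
#' allele from each parent independently per marker (markers are unlinked).
#' Markers are placed on 18 autosomes with positions sorted within chromosome.
#'
#' @param ped Pedigree tibble from [simulate_pedigree()] (topological order).
#' @param cfg A [sim_config()].
#' @return A `geno_matrix`: list with `dosage` (animals x markers integer
#'   matrix, entries 0/1/2), `map` (tibble `marker`, `chrom`, `pos`) and
#'   `founder_freq` (per-marker founder allele frequency).
#' @export
simulate_genotypes <- function(ped, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pidx <- parent_index(ped)
  n <- nrow(ped)
  p <- cfg$n_markers
  with_seed(derive_seed(cfg$seed, "genotypes"), {
    freq <- runif(p, cfg$maf_range[1], cfg$maf_range[2])
    h1 <- matrix(0L, n, p)
    h2 <- matrix(0L, n, p)
    founders <- which(pidx$sire == 0L & pidx$dam == 0L)
    h1[founders, ] <- matrix(rbinom(length(founders) * p, 1L, rep(freq, each = length(founders))),
                             length(founders), p)
    h2[founders, ] <- matrix(rbinom(length(founders) * p, 1L, rep(freq, each = length(founders))),
                             length(founders), p)
    for (i in seq_len(n)) {
      s <- pidx$sire[i]; d <- pidx$dam[i]
      if (s == 0L && d == 0L) next
      # one allele from each parent, independent Mendelian draw per marker
      ms <- runif(p) < 0.5
      md <- runif(p) < 0.5
      h1[i, ] <- ifelse(ms, h1[s, ], h2[s, ])
      h2[i, ] <- ifelse(md, h1[d, ], h2[d, ])
    }
    dos <- h1 + h2
    chrom <- sort(rep_len(seq_len(18L), p))
    pos <- integer(p)
    for (cc in unique(chrom)) {
      k <- sum(chrom == cc)
      pos[chrom == cc] <- sort(sample.int(2e8L, k))
    }
    marker <- sprintf("SNP%05d", seq_len(p))
    dimnames(dos) <- list(ped$animal, marker)
    geno_matrix(dos, map = tibble::tibble(marker = marker, chrom = chrom, pos = pos),
                founder_freq = setNames(freq, marker))
  })
}

#' Construct a genotype-matrix container
#'
#' @param dosage Animals x markers matrix of dosages (0/1/2 or NA), with
#'   animal ids as rownames and marker ids as colnames.
#' @param map Optional tibble of marker metadata (`marker`, `chrom`, `pos`).
#' @param founder_freq Optional named numeric vector of simulation founder
#'   allele frequencies.
#' @return A `geno_matrix` object.
#' @export
geno_matrix <- function(dosage, map = NULL, founder_freq = NULL) {
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    abort("`dosage` needs animal rownames and marker colnames")
  }
  if (anyDuplicated(rownames(dosage)) || anyDuplicated(colnames(dosage))) {
    abort("animal and marker ids must be unique")
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2)) {
    abort("non-missing dosages must be 0, 1 or 2")
  }
  if (is.null(map)) {
    map <- tibble::tibble(marker = colnames(dosage), chrom = NA_integer_,
                          pos = seq_len(ncol(dosage)))
  }
  if (!identical(map$marker, colnames(dosage))) {
    abort("`map$marker` must match dosage colnames in order")
  }
  structure(list(dosage = dosage, map = map, founder_freq = founder_freq),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  nm <- sum(is.na(x$dosage))
  cat(sprintf("<geno_matrix> %d animals x %d markers (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * nm / length(x$dosage)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Simulate repeated phenotypes under the repeatability model
#'
#' True breeding values are built from a random subset of `n_qtl` markers with
#' effects drawn from N(0, sigma2_a / (2 * sum p_q (1 - p_q))) at the founder
#' allele frequencies, so that the founder additive variance equals
#' `sigma2_a` in expectation. Each female carries 1-3 records (per
#' `records_per_sow`): record value = herd-year-season effect + breeding value
#' + permanent-environment effect + residual.
#'
#' @param ped Pedigree tibble.
#' @param geno `geno_matrix` from [simulate_genotypes()] (complete dosages).
#' @param cfg A [sim_config()].
#' @return List with `records` (tibble `animal`, `parity`, `hys`, `value`) and
#'   `truth` (list with `true_bv`, `true_pe` tibbles and `qtl` effect table).
#' @export
simulate_phenotypes <- function(ped, geno, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(geno, "geno_matrix"))
  if (cfg$n_qtl == 0L && cfg$sigma2_a > 0) {
    abort("`n_qtl` = 0 is incompatible with positive additive variance")
  }
  if (anyNA(geno$dosage)) abort("phenotype simulation needs complete genotypes")
  with_seed(derive_seed(cfg$seed, "phenotypes"), {
    p_all <- geno$founder_freq %||% (colMeans(geno$dosage) / 2)
    qtl_idx <- if (cfg$n_qtl > 0L) sort(sample.int(ncol(geno$dosage), cfg$n_qtl)) else integer()
    if (cfg$n_qtl > 0L && cfg$sigma2_a > 0) {
      pq <- p_all[qtl_idx]
      denom <- 2 * sum(pq * (1 - pq))
      alpha <- rnorm(cfg$n_qtl, 0, sqrt(cfg$sigma2_a / denom))
      bv <- drop(geno$dosage[, qtl_idx, drop = FALSE] %*% alpha)
      bv <- bv - mean(bv[ped$generation == 0L])   # express BV relative to founder mean
    } else {
      alpha <- numeric(length(qtl_idx))
      bv <- numeric(nrow(ped))
    }
    names(bv) <- ped$animal
    sows <- ped$animal[ped$sex == "female"]
    pe <- rnorm(length(sows), 0, sqrt(cfg$sigma2_pe))
    names(pe) <- sows
    hys_eff <- rnorm(cfg$n_hys_levels, 0, cfg$hys_effect_sd)
    n_rec <- sample(cfg$records_per_sow, length(sows), replace = TRUE)
    animal <- rep(sows, n_rec)
    parity <- unlist(lapply(n_rec, seq_len), use.names = FALSE)
    hys <- sample.int(cfg$n_hys_levels, length(animal), replace = TRUE)
    value <- hys_eff[hys] + bv[animal] + pe[animal] +
      rnorm(length(animal), 0, sqrt(cfg$sigma2_e))
    records <- tibble::tibble(
      animal = animal, parity = parity,
      hys = factor(sprintf("HYS%02d", hys), levels = sprintf("HYS%02d", seq_len(cfg$n_hys_levels))),
      value = as.numeric(value)
    )
    truth <- list(
      true_bv = tibble::tibble(animal = ped$animal, true_bv = unname(bv)),
      true_pe = tibble::tibble(animal = sows, true_pe = unname(pe)),
      qtl = tibble::tibble(marker = colnames(geno$dosage)[qtl_idx], effect = alpha),
      hys_effects = tibble::tibble(hys = sprintf("HYS%02d", seq_len(cfg$n_hys_levels)),
                                   effect = hys_eff)
    )
    list(records = records, truth = truth)
  })
}

#' Flag a reproducible subset of animals as genotyped
#'
#' @param ped Pedigree tibble.
#' @param cfg A [sim_config()]; `genotyped_fraction` and `seed` are used.
#' @return Character vector of genotyped animal ids.
#' @export
assign_genotyping_status <- function(ped, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(ped)
  k <- round(cfg$genotyped_fraction * n)
  with_seed(derive_seed(cfg$seed, "genotyping"), {
    sort(sample(ped$animal, k))
  })
}

#' Inject missing genotype calls
#'
#' Entries of the selected markers (default: all) are set missing
#' independently with probability `marker_rate`; entries of the selected
#' animals with probability `animal_rate`. The input object is not modified.
#'
#' @param geno A `geno_matrix`.
#' @param marker_rate,animal_rate Missingness probabilities in \[0, 1\].
#' @param seed Integer seed.
#' @param markers,animals Optional ids restricting which markers/animals are
#'   affected.
#' @return A new `geno_matrix` with NA entries.
#' @export
inject_missingness <- function(geno, marker_rate = 0, animal_rate = 0, seed = 1L,
                               markers = NULL, animals = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  assert_scalar_num(marker_rate, "marker_rate", 0, 1)
  assert_scalar_num(animal_rate, "animal_rate", 0, 1)
  dos <- geno$dosage
  with_seed(seed, {
    if (marker_rate > 0) {
      cols <- if (is.null(markers)) seq_len(ncol(dos)) else match(markers, colnames(dos))
      if (anyNA(cols)) abort("unknown marker ids in `markers`")
      mask <- matrix(runif(nrow(dos) * length(cols)) < marker_rate, nrow(dos))
      dos[, cols][mask] <- NA_integer_
    }
    if (animal_rate > 0) {
      rows <- if (is.null(animals)) seq_len(nrow(dos)) else match(animals, rownames(dos))
      if (anyNA(rows)) abort("unknown animal ids in `animals`")
      mask <- matrix(runif(length(rows) * ncol(dos)) < animal_rate, length(rows))
      dos[rows, ][mask] <- NA_integer_
    }
  })
  geno_matrix(dos, map = geno$map, founder_freq = geno$founder_freq)
}

#' Simulate a complete benchmark dataset
#'
#' Convenience wrapper running pedigree, genotype and phenotype simulation and
#' genotyping-status assignment under one configuration.
#'
#' @param cfg A [sim_config()].
#' @return A `gs_dataset`: list with `pedigree`, `genotypes`, `records`,
#'   `truth`, `genotyped_ids` and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  phen <- simulate_phenotypes(ped, geno, cfg)
  structure(
    list(pedigree = ped, genotypes = geno, records = phen$records,
         truth = phen$truth, genotyped_ids = assign_genotyping_status(ped, cfg),
         config = cfg),
    class = "gs_dataset"
  )
}

#' @export
print.gs_dataset <- function(x, ...) {
  cat(sprintf("<gs_dataset> %d animals (%d genotyped), %d markers, %d records\n",
              nrow(x$pedigree), length(x$genotyped_ids),
              ncol(x$genotypes$dosage), nrow(x$records)))
  if (!is.null(x$yc)) cat(sprintf("  corrected phenotypes for %d animals\n", nrow(x$yc)))
  invisible(x)
}
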