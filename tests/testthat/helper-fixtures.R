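# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Desk-scale dataset (~280 animals) with corrected phenotypes and the
# genomic / single-step matrices prepared.
small_dataset <- function() {
  fixture("small_dataset", function() {
    cfg <- sim_config(n_founders = 60L, n_generations = 2L,
                      offspring_per_mating = 3L, n_markers = 300L,
                      n_qtl = 40L, records_per_sow = 2L, n_hys_levels = 5L,
                      seed = 42L)
    prepare_benchmark(simulate_dataset(cfg))
  })
}

# Tiny pedigree + records for MME-level checks.
toy_records <- function() {
  fixture("toy_records", function() {
    cfg <- sim_config(n_founders = 10L, n_generations = 2L,
                      offspring_per_mating = 2L, n_markers = 50L,
                      n_qtl = 10L, records_per_sow = 2L, n_hys_levels = 3L,
                      seed = 7L)
    ped <- simulate_pedigree(cfg)
    geno <- simulate_genotypes(ped, cfg)
    phen <- simulate_phenotypes(ped, geno, cfg)
    list(cfg = cfg, ped = ped, geno = geno, records = phen$records,
         truth = phen$truth)
  })
}

# Hand-built pedigree with a full-sib mating: founders 1,2; full sibs 3,4;
# their offspring 5 (inbred F = 0.25); plus an outbred animal 6.
fullsib_pedigree <- function() {
  tibble::tibble(
    animal = c("P1", "P2", "S3", "S4", "O5", "U6"),
    sire = c(NA, NA, "P1", "P1", "S3", NA),
    dam = c(NA, NA, "P2", "P2", "S4", NA),
    sex = c("male", "female", "male", "female", "male", "female"),
    birth_date = as.Date("2016-01-01") + 0:5,
    generation = c(0L, 0L, 1L, 1L, 2L, 0L)
  )
}

# Dense GLS solution of the repeatability model, the independent oracle for
# the MME solver: beta = (X'V^-1 X)^-1 X'V^-1 y, a = s2a A Za' V^-1 (y - Xb),
# pe = s2pe Zpe' V^-1 (y - Xb).
gls_oracle <- function(ped, records, vc) {
  hys <- factor(records$hys)
  X <- stats::model.matrix(~ 0 + hys)
  A <- build_A(ped)
  Za <- outer(records$animal, ped$animal, "==") * 1
  pe_ids <- sort(unique(records$animal))
  Zpe <- outer(records$animal, pe_ids, "==") * 1
  V <- Za %*% A %*% t(Za) * vc$sigma2_a + tcrossprod(Zpe) * vc$sigma2_pe +
    diag(nrow(records)) * vc$sigma2_e
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% records$value)
  r <- records$value - X %*% b
  a <- vc$sigma2_a * A %*% t(Za) %*% Vi %*% r
  pe <- vc$sigma2_pe * t(Zpe) %*% Vi %*% r
  list(fixed = drop(b), ebv = setNames(drop(a), ped$animal),
       pe = setNames(drop(pe), pe_ids))
}
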