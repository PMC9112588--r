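# Repeatability-model REML and mixed-model equations.

test_that("MME solution equals generalized least squares on a small dataset", {
  toy <- toy_records()
  keep <- toy$ped$animal[1:14]
  ped <- toy$ped[toy$ped$animal %in% keep, ]
  records <- toy$records[toy$records$animal %in% ped$animal, ][1:10, ]
  records$hys <- droplevels(records$hys)
  vc <- variance_components(1.2, 0.4, 8.5)
  sol <- solve_mme(ped, records, vc)
  oracle <- gls_oracle(ped, records, vc)
  expect_equal(sol$fixed_effects$estimate, unname(oracle$fixed), tolerance = 1e-8)
  expect_equal(sol$ebv$ebv, unname(oracle$ebv[sol$ebv$animal]), tolerance = 1e-8)
  expect_equal(sol$pe_hat$pe_hat, unname(oracle$pe[sol$pe_hat$animal]),
               tolerance = 1e-8)
  # residual definition: value - fitted
  expect_equal(sol$residuals$residual,
               records$value - sol$residuals$fitted)
})

test_that("infinite shrinkage drives every EBV to zero", {
  toy <- toy_records()
  vc <- variance_components(1e-8, 0.3, 9)   # ratio sigma2_e/sigma2_a = 9e8
  sol <- solve_mme(toy$ped, toy$records, vc)
  expect_lt(max(abs(sol$ebv$ebv)), 1e-6)
})

test_that("recordless offspring receive the parent-average EBV", {
  toy <- toy_records()
  ped <- toy$ped
  records <- toy$records
  # add a brand-new terminal offspring with no records and no descendants
  ped2 <- dplyr::bind_rows(ped, tibble::tibble(
    animal = "NEWKID", sire = ped$animal[ped$sex == "male"][1],
    dam = ped$animal[ped$sex == "female"][1], sex = "female",
    birth_date = max(ped$birth_date) + 1, generation = max(ped$generation) + 1L))
  vc <- variance_components(1.2, 0.3, 9)
  sol <- solve_mme(ped2, records, vc)
  ebv <- setNames(sol$ebv$ebv, sol$ebv$animal)
  expect_equal(unname(ebv["NEWKID"]),
               unname((ebv[ped2$sire[nrow(ped2)]] + ebv[ped2$dam[nrow(ped2)]]) / 2),
               tolerance = 1e-10)
})

test_that("an empty herd-year-season level is rejected by name", {
  toy <- toy_records()
  records <- toy$records
  records$hys <- factor(records$hys, levels = c(levels(records$hys), "HYS99"))
  expect_error(solve_mme(toy$ped, records, variance_components(1, 0.3, 9)),
               "HYS99")
  orphan <- dplyr::mutate(toy$records[1, ], animal = "GHOST")
  expect_error(solve_mme(toy$ped, dplyr::bind_rows(toy$records, orphan),
                         variance_components(1, 0.3, 9)),
               "GHOST")
})

test_that("AI-REML ascends monotonically and matches its own gradient", {
  toy <- toy_records()
  ws <- gsbench:::repeatability_design(toy$ped, toy$records)
  vc <- variance_components(0.8, 0.5, 7)
  pieces <- gsbench:::reml_loglik_pieces(ws, vc)
  traces <- gsbench:::mme_traces(ws, pieces$Ch)
  grad <- gsbench:::reml_gradient(ws, vc, pieces$sol, traces)$grad
  fd <- vapply(1:3, function(k) {
    h <- 1e-5
    th <- c(vc$sigma2_a, vc$sigma2_pe, vc$sigma2_e)
    up <- th; up[k] <- up[k] + h
    dn <- th; dn[k] <- dn[k] - h
    (gsbench:::reml_loglik_pieces(ws, variance_components(up[1], up[2], up[3]))$loglik -
       gsbench:::reml_loglik_pieces(ws, variance_components(dn[1], dn[2], dn[3]))$loglik) / (2 * h)
  }, numeric(1))
  expect_equal(grad, fd, tolerance = 1e-5)
  # optimizer contract: restricted likelihood at the optimum >= at the start
  init <- variance_components(0.8, 0.5, 7)
  fit <- suppressWarnings(estimate_reml(toy$ped, toy$records, init = init))
  expect_gte(fit$loglik, gsbench:::reml_loglik_pieces(ws, init)$loglik)
})

test_that("REML estimates are invariant to starting values", {
  ds <- small_dataset()
  fits <- lapply(list(
    variance_components(0.5, 0.5, 5),
    variance_components(3, 0.05, 12),
    variance_components(1.26, 0.29, 8.95)
  ), function(init) estimate_reml(ds$pedigree, ds$records, init = init))
  for (k in 2:3) {
    expect_equal(fits[[k]]$sigma2_a, fits[[1]]$sigma2_a, tolerance = 1e-6)
    expect_equal(fits[[k]]$sigma2_pe, fits[[1]]$sigma2_pe, tolerance = 1e-6)
    expect_equal(fits[[k]]$sigma2_e, fits[[1]]$sigma2_e, tolerance = 1e-6)
  }
  expect_true(fits[[1]]$converged)
})

test_that("MME solution is invariant to record order and animal relabeling", {
  toy <- toy_records()
  vc <- variance_components(1.1, 0.35, 8.8)
  sol <- solve_mme(toy$ped, toy$records, vc)
  perm <- sample(nrow(toy$records))
  sol_perm <- solve_mme(toy$ped, toy$records[perm, ], vc)
  expect_equal(sol_perm$ebv, sol$ebv, tolerance = 1e-10)
  # relabel animals (prefix swap), keeping topological order
  relabel <- function(x) ifelse(is.na(x), NA_character_, paste0("X", x))
  ped2 <- dplyr::mutate(toy$ped, animal = relabel(animal),
                        sire = relabel(sire), dam = relabel(dam))
  rec2 <- dplyr::mutate(toy$records, animal = relabel(animal))
  sol2 <- solve_mme(ped2, rec2, vc)
  expect_equal(sol2$ebv$ebv, sol$ebv$ebv, tolerance = 1e-10)
})

test_that("null additive variance is recovered at the boundary", {
  # a deep pedigree separates the additive from the permanent-environment
  # component; under sigma2_a = 0 the estimate should collapse to the floor
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_founders = 100L, n_generations = 3L,
                      offspring_per_mating = 3L, n_markers = 40L, n_qtl = 10L,
                      sigma2_a = 0, sigma2_pe = 0.5, sigma2_e = 9,
                      records_per_sow = 3L, n_hys_levels = 4L, seed = 600L + r)
    ped <- simulate_pedigree(cfg)
    geno <- simulate_genotypes(ped, cfg)
    phen <- simulate_phenotypes(ped, geno, cfg)
    fit <- estimate_reml(ped, phen$records)
    if (fit$sigma2_a < 0.05 * fit$sigma2_e) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.85)
})

test_that("EBV accuracy increases with heritability", {
  cors <- vapply(c(0.05, 0.12, 0.3), function(h2) {
    s2a <- h2 * 10.5
    s2e <- 10.5 - s2a - 0.29
    cfg <- sim_config(n_founders = 80L, n_generations = 2L,
                      offspring_per_mating = 3L, n_markers = 200L, n_qtl = 50L,
                      sigma2_a = s2a, sigma2_pe = 0.29, sigma2_e = s2e,
                      records_per_sow = 2L, n_hys_levels = 4L, seed = 202L)
    ped <- simulate_pedigree(cfg)
    geno <- simulate_genotypes(ped, cfg)
    phen <- simulate_phenotypes(ped, geno, cfg)
    sol <- solve_mme(ped, phen$records,
                     variance_components(s2a, 0.29, s2e))
    bv <- setNames(phen$truth$true_bv$true_bv, phen$truth$true_bv$animal)
    cor(sol$ebv$ebv, bv[sol$ebv$animal])
  }, numeric(1))
  expect_true(all(cors > 0))
  expect_true(all(diff(cors) > 0))
})

test_that("corrected phenotypes add the mean own residual to the EBV", {
  # arithmetic contract on a constructed solution
  sol <- structure(list(
    ebv = tibble::tibble(animal = c("A", "B", "C"), ebv = c(1.0, 2.0, -1.0)),
    residuals = tibble::tibble(animal = c("A", "A", "B"),
                               parity = c(1L, 2L, 1L),
                               hys = factor(c("h1", "h2", "h1")),
                               value = c(0, 0, 0), fitted = c(0, 0, 0),
                               residual = c(0.4, -0.2, 0))
  ), class = "blup_solution")
  yc <- corrected_phenotypes(sol)
  expect_equal(yc$y_c[yc$animal == "A"], 1.1)   # 1.0 + mean(0.4, -0.2)
  expect_equal(yc$y_c[yc$animal == "B"], 2.0)   # zero residual
  expect_equal(yc$y_c[yc$animal == "C"], -1.0)  # no records -> EBV
  expect_false(yc$has_records[yc$animal == "C"])
  expect_true(all(yc$has_records[yc$animal != "C"]))
})

test_that("tidiers expose variance components and fit summary", {
  ds <- small_dataset()
  td <- tidy(ds$vc)
  expect_equal(td$component, c("sigma2_a", "sigma2_pe", "sigma2_e"))
  gl <- glance(ds$vc)
  expect_equal(gl$h2,
               ds$vc$sigma2_a / (ds$vc$sigma2_a + ds$vc$sigma2_pe + ds$vc$sigma2_e))
  expect_true(gl$converged)
})
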