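# Validation protocol, metrics, Hotelling-Williams test, QC and concordance.

test_that("a 2,566-id plan yields five folds of 513/514 partitioning the set", {
  ids <- sprintf("P%04d", 1:2566)
  plan <- make_cv_plan(ids, n_folds = 5L, n_replicates = 2L, seed = 3L)
  expect_equal(nrow(plan), 10L)
  for (rep_i in 1:2) {
    sub <- plan[plan$replicate == rep_i, ]
    sizes <- lengths(sub$validation_ids)
    expect_setequal(sizes, c(514L, 513L))
    expect_equal(sort(sizes, decreasing = TRUE), c(514L, rep(513L, 4)))
    all_val <- unlist(sub$validation_ids)
    expect_equal(length(all_val), 2566L)        # pairwise disjoint
    expect_setequal(all_val, ids)               # union = everything
    # reference is the complement within the replicate
    expect_setequal(c(sub$validation_ids[[1]], sub$reference_ids[[1]]), ids)
  }
})

test_that("cross-validation plans are reproducible and hashed", {
  ids <- letters
  p1 <- make_cv_plan(ids, n_folds = 5L, n_replicates = 3L, seed = 11L)
  p2 <- make_cv_plan(ids, n_folds = 5L, n_replicates = 3L, seed = 11L)
  expect_identical(p1$validation_ids, p2$validation_ids)
  expect_identical(attr(p1, "plan_hash"), attr(p2, "plan_hash"))
  p3 <- make_cv_plan(ids, n_folds = 5L, n_replicates = 3L, seed = 12L)
  expect_false(identical(attr(p1, "plan_hash"), attr(p3, "plan_hash")))
  expect_error(make_cv_plan(letters[1:3], n_folds = 5L), "folds")
})

test_that("forward splits follow the birth-date cutoff and reject empty sides", {
  ped <- small_dataset()$pedigree
  split <- make_forward_split(ped, cutoff_date = "2017-12-31")
  expect_setequal(split$validation_ids, ped$animal[ped$birth_date > as.Date("2017-12-31")])
  expect_setequal(c(split$reference_ids, split$validation_ids), ped$animal)
  expect_error(make_forward_split(ped, cutoff_date = max(ped$birth_date) + 1),
               "empty validation")
  expect_error(make_forward_split(ped, cutoff_date = min(ped$birth_date) - 1),
               "empty reference")
  # restricting to a subset restricts both sides
  sub <- ped$animal[seq(1, nrow(ped), by = 3)]
  s2 <- make_forward_split(ped, cutoff_date = "2017-12-31", ids = sub)
  expect_true(all(c(s2$reference_ids, s2$validation_ids) %in% sub))
})

test_that("accuracy, unbiasedness and error metrics match their formulas", {
  y <- c(1.2, -0.5, 2.0, 0.1, -1.3)
  expect_equal(accuracy(y, y), 1.0)
  expect_equal(accuracy(y, -y), -1.0)
  set.seed(4)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(accuracy(a, b),
               sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))
  expect_equal(unbiasedness(y, y), 1.0)
  expect_equal(unbiasedness(y, 0.5 * y), 2.0)
  expect_equal(unbiasedness(a, b), cov(a, b) / var(b))
  expect_equal(unbiasedness(a, b), unname(coef(lm(a ~ b))[2]))
  expect_equal(mse_mae(y, y), c(mse = 0, mae = 0))
  expect_equal(mse_mae(c(2, 4), c(1, 2)), c(mse = 2.5, mae = 1.5))
  em <- mse_mae(a, b)
  expect_lte(em[["mae"]]^2, em[["mse"]])  # Jensen
  expect_warning(accuracy(rep(1, 5), y), "zero variance")
})

test_that("Hotelling-Williams statistic vanishes for equal correlations", {
  out <- hotelling_williams(0.4, 0.4, 0.6, 100)
  expect_equal(out$t, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$df, 97)
  expect_error(hotelling_williams(0.9, -0.9, 0.9, 100), "incoherent")
  expect_error(hotelling_williams(0.5, 0.4, 0.3, 3), "n > 3")
  expect_error(hotelling_williams(1, 0.4, 0.3, 50), "correlations")
  # direction: a clearly larger r12 gives positive t and small p
  out2 <- hotelling_williams(0.6, 0.2, 0.5, 200)
  expect_gt(out2$t, 0)
  expect_lt(out2$p_value, 0.01)
})

test_that("QC removes exactly the low-MAF and low-call-rate markers", {
  n <- 100L
  dos <- cbind(
    m_lowmaf = c(1L, rep(0L, n - 1L)),           # MAF 0.005
    m_lowcr = c(rep(NA_integer_, 15L), rep(1L, n - 15L)),  # call rate 0.85
    m_ok1 = rep(c(0L, 1L, 2L, 1L), n / 4),
    m_ok2 = rep(c(2L, 1L, 0L, 1L), n / 4)
  )
  rownames(dos) <- sprintf("A%03d", 1:n)
  # one animal with 50% missing calls on the surviving markers
  dos["A001", c("m_ok1")] <- NA_integer_
  geno <- geno_matrix(dos)
  out <- qc_filter(geno)
  expect_setequal(colnames(out$genotypes$dosage), c("m_ok1", "m_ok2"))
  expect_false("A001" %in% rownames(out$genotypes$dosage))
  expect_equal(out$report$removed, c(1L, 1L, 1L))
  # a clean matrix passes untouched with an all-zero report
  clean <- geno_matrix(dos[-1, c("m_ok1", "m_ok2")])
  out2 <- qc_filter(clean)
  expect_identical(out2$genotypes$dosage, clean$dosage)
  expect_equal(sum(out2$report$removed), 0L)
  all_bad <- geno_matrix(dos[, "m_lowmaf", drop = FALSE])
  expect_error(qc_filter(all_bad), "every marker")
})

test_that("concordance metrics match direct computation", {
  toy <- toy_records()
  g <- toy$geno
  expect_equal(concordance(g, g)$overall$cr, 1.0)
  expect_equal(concordance(g, g)$overall$cor, 1.0)
  # flip 3 of the first 20 calls of one marker
  dos2 <- g$dosage
  dos2[1:3, 5] <- (dos2[1:3, 5] + 1L) %% 3L
  g2 <- geno_matrix(dos2, map = g$map)
  out <- concordance(g2, g)
  expect_equal(out$overall$cr, mean(dos2 == g$dosage))
  expect_equal(out$overall$cor, cor(as.vector(dos2), as.vector(g$dosage)))
  pm <- out$per_marker
  expect_equal(pm$cr[pm$marker == colnames(dos2)[5]],
               mean(dos2[, 5] == g$dosage[, 5]))
  # 10 calls with 1 mismatch -> CR 0.9
  a <- geno_matrix(matrix(c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L, 1L, 2L), 5, 2,
                          dimnames = list(paste0("s", 1:5), c("x", "y"))))
  b_dos <- a$dosage; b_dos[1, 1] <- 2L
  b <- geno_matrix(b_dos)
  expect_equal(concordance(b, a)$overall$cr, 0.9)
})

test_that("the benchmark driver reports every method on every fold", {
  ds <- small_dataset()
  plan <- make_cv_plan(rownames(ds$G), n_folds = 5L, n_replicates = 2L,
                       seed = 2L)
  perfect <- function(data, ref, val) data$yc$y_c[match(val, data$yc$animal)]
  noisy <- function(data, ref, val) {
    data$yc$y_c[match(val, data$yc$animal)] + rnorm(length(val), 0, 0.1)
  }
  res <- run_benchmark(ds, list(perfect = perfect, perfect_too = perfect,
                                noisy = noisy), plan)
  expect_equal(nrow(res$metrics), 3L * 2L * 5L)
  expect_equal(res$metrics$accuracy[res$metrics$method == "perfect"],
               rep(1, 10), tolerance = 1e-12)
  expect_true(all(res$metrics$mse[res$metrics$method == "perfect"] == 0))
  # identical methods: Hotelling-Williams p-value 1 for the pair
  pw <- res$pairwise
  pp <- pw[pw$method_1 == "perfect" & pw$method_2 == "perfect_too", ]
  expect_true(all(pp$p_value == 1))
  # per-replicate aggregate equals the mean of its five fold rows
  agg <- res$metrics |>
    dplyr::filter(method == "noisy") |>
    dplyr::group_by(replicate) |>
    dplyr::summarise(m = mean(accuracy))
  manual <- tapply(res$metrics$accuracy[res$metrics$method == "noisy"],
                   res$metrics$replicate[res$metrics$method == "noisy"], mean)
  expect_equal(agg$m, as.numeric(manual))
  expect_identical(res$plan_hash, attr(plan, "plan_hash"))
})

test_that("method failures are recorded while the run continues", {
  ds <- small_dataset()
  plan <- make_cv_plan(rownames(ds$G), n_folds = 5L, n_replicates = 1L,
                       seed = 5L)
  boom <- function(data, ref, val) stop("deliberate failure")
  ok <- function(data, ref, val) data$yc$y_c[match(val, data$yc$animal)]
  res <- run_benchmark(ds, list(ok = ok, boom = boom), plan)
  expect_equal(nrow(res$failures), 5L)
  expect_equal(nrow(res$metrics), 5L)
  expect_true(all(res$metrics$method == "ok"))
})

test_that("the standard methods run end to end on a desk-scale fold", {
  ds <- small_dataset()
  gids <- rownames(ds$G)
  plan <- list(reference_ids = head(gids, -30), validation_ids = tail(gids, 30))
  res <- run_benchmark(
    ds, c("gblup", "ssgblup", "krr", "rf"), plan,
    params = list(krr = krr_params(lam = 0.1, gamma = 1e-3),
                  rf = rf_params(n_estimators = 30L)),
    hs_cfg = hs_config(preset = "test", seed = 1L))
  expect_equal(nrow(res$metrics), 4L)
  expect_true(all(is.finite(res$metrics$accuracy)))
  expect_true(all(res$metrics$mse > 0))
  expect_s3_class(autoplot(res), "ggplot")
})
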