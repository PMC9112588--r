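# Validation protocols: repeated five-fold cross-validation plans, the
# forward (younger animals) split, and the benchmark driver.

#' Repeated cross-validation plan
#'
#' Randomly partitions the ids into `n_folds` validation groups per
#' replicate; group sizes differ by at most one, with the remainder animals
#' assigned to the earliest folds. The identical plan is served to every
#' method benchmarked.
#'
#' @param ids Character vector of (genotyped) animal ids.
#' @param n_folds,n_replicates Protocol dimensions (default 5-fold, 20
#'   replicates).
#' @param seed Master seed; each replicate derives its own child seed.
#' @return A `cv_plan` tibble with columns `replicate`, `fold`,
#'   `validation_ids`, `reference_ids` (list-columns) and `seed`, with the
#'   plan hash in attribute `plan_hash`.
#' @export
make_cv_plan <- function(ids, n_folds = 5L, n_replicates = 20L, seed = 1L) {
  n_folds <- assert_count(n_folds, "n_folds", 2L)
  n_replicates <- assert_count(n_replicates, "n_replicates", 1L)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) abort("duplicated ids in cross-validation plan")
  n <- length(ids)
  if (n_folds > n) abort("more folds than ids")
  base <- n %/% n_folds
  sizes <- rep(base, n_folds) + c(rep(1L, n %% n_folds),
                                  rep(0L, n_folds - n %% n_folds))
  plan <- purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
    rep_seed <- derive_seed(seed, paste0("cv-replicate-", rep_i))
    shuffled <- with_seed(rep_seed, sample(ids))
    stops <- cumsum(sizes)
    starts <- c(1L, head(stops, -1L) + 1L)
    tibble::tibble(
      replicate = rep_i,
      fold = seq_len(n_folds),
      validation_ids = purrr::map2(starts, stops, function(a, b) shuffled[a:b]),
      reference_ids = purrr::map2(starts, stops,
                                  function(a, b) shuffled[-(a:b)]),
      seed = rep_seed
    )
  })
  class(plan) <- c("cv_plan", class(plan))
  attr(plan, "plan_hash") <- rlang::hash(plan[c("replicate", "fold", "validation_ids")])
  plan
}

#' Forward validation split by birth date
#'
#' Validation animals are those born strictly after `cutoff_date`; the
#' remainder form the reference. Restricted to `ids` when supplied (e.g. the
#' genotyped set).
#'
#' @param ped Pedigree tibble with `birth_date`.
#' @param cutoff_date Cutoff (`Date` or string); default end of January 2020
#'   so that animals born after January 2020 are validated.
#' @param ids Optional subset of candidate animals.
#' @return List with `reference_ids` and `validation_ids`.
#' @export
make_forward_split <- function(ped, cutoff_date = "2020-01-31", ids = NULL) {
  cutoff <- as.Date(cutoff_date)
  pool <- if (is.null(ids)) ped else ped[ped$animal %in% ids, ]
  val <- pool$animal[pool$birth_date > cutoff]
  ref <- setdiff(pool$animal, val)
  if (!length(val)) abort("empty validation set: no animals born after the cutoff")
  if (!length(ref)) abort("empty reference set: all animals born after the cutoff")
  list(reference_ids = ref, validation_ids = val)
}

# ---- benchmark driver ------------------------------------------------------

# Fit one method on one fold and return predictions for the validation ids.
benchmark_predict <- function(method, data, ref_ids, val_ids, opts) {
  yc <- data$yc
  dos <- data$genotypes$dosage
  if (is.function(method)) return(method(data, ref_ids, val_ids))
  switch(method,
    gblup = {
      fit <- fit_gblup(yc, data$G, ref_ids)
      fit$predictions$pv[match(val_ids, fit$predictions$animal)]
    },
    ssgblup = {
      # non-genotyped animals with phenotypes join the reference
      extra <- setdiff(yc$animal[yc$has_records], rownames(data$G))
      fit <- fit_ssgblup(yc, data$H_inv, union(ref_ids, extra))
      fit$predictions$pv[match(val_ids, fit$predictions$animal)]
    },
    bayeshe = {
      fit <- fit_bayeshe(yc, data$genotypes, ref_ids, cfg = opts$hs_config)
      fit$predictions$pv[match(val_ids, fit$predictions$animal)]
    },
    svr = ,
    krr = ,
    rf = ,
    adaboost_svr = ,
    adaboost_krr = {
      X <- dos[ref_ids, , drop = FALSE]
      yref <- yc$y_c[match(ref_ids, yc$animal)]
      params <- if (isTRUE(opts$tune)) {
        grid_search(X, yref, method, grid = opts$grids[[method]],
                    seed = opts$seed)$best
      } else {
        opts$params[[method]] %||% switch(method,
          svr = svr_params(), krr = krr_params(), rf = rf_params(),
          adaboost_svr = adaboost_params(base = "svr"),
          adaboost_krr = adaboost_params(base = "krr"))
      }
      fit <- ml_fit(method, X, yref, params)
      unname(predict(fit, dos[val_ids, , drop = FALSE]))
    },
    abort(sprintf("unknown method `%s`", method))
  )
}

#' Prepare a dataset for benchmarking
#'
#' Fits the pedigree repeatability model by AI-REML, derives corrected
#' phenotypes and builds the genomic and single-step relationship matrices
#' once for the whole benchmark (allele frequencies from the full genotyped
#' set).
#'
#' @param dataset A `gs_dataset` from [simulate_dataset()] or assembled from
#'   files.
#' @param blend_w Weight of the pedigree block when blending G.
#' @param vc Optional `varcomp` to skip REML.
#' @return The dataset augmented with `yc`, `vc`, `G`, `H_inv`, `blup`.
#' @export
prepare_benchmark <- function(dataset, blend_w = 0.05, vc = NULL) {
  stopifnot(inherits(dataset, "gs_dataset"))
  if (is.null(vc)) vc <- estimate_reml(dataset$pedigree, dataset$records)
  sol <- solve_mme(dataset$pedigree, dataset$records, vc)
  dataset$yc <- corrected_phenotypes(sol)
  dataset$vc <- vc
  dataset$blup <- sol
  gids <- intersect(dataset$genotyped_ids, rownames(dataset$genotypes$dosage))
  G0 <- build_G(dataset$genotypes$dosage[gids, , drop = FALSE])
  ss <- single_step_matrices(dataset$pedigree, G0, w = blend_w)
  dataset$G <- ss$Gw
  dataset$H_inv <- ss$H_inv
  dataset
}

#' Run the prediction benchmark
#'
#' Executes every method on every fold of a shared [make_cv_plan()] (or a
#' single forward split), computing accuracy (Pearson r of corrected
#' phenotype and prediction), unbiasedness (regression slope of y_c on PV),
#' MSE and MAE per fold, and the Hotelling-Williams test on predictions
#' pooled per replicate for every method pair. A method failure on a fold is
#' recorded and the run continues.
#'
#' @param dataset A dataset prepared by [prepare_benchmark()].
#' @param methods Character vector among `"gblup"`, `"ssgblup"`, `"bayeshe"`,
#'   `"svr"`, `"krr"`, `"rf"`, `"adaboost_svr"`, `"adaboost_krr"`, or a named
#'   list whose elements may also be functions
#'   `f(dataset, reference_ids, validation_ids) -> predictions`.
#' @param plan A `cv_plan`, or a forward split from [make_forward_split()].
#' @param tune Run [grid_search()] per fold instead of fixed parameters.
#' @param grids Optional named list of grids per method (when tuning).
#' @param params Optional named list of fixed parameter objects per method.
#' @param hs_cfg Chain settings for `"bayeshe"`.
#' @param seed Seed forwarded to per-fold tuning.
#' @param verbose Print progress.
#' @return A `benchmark_result`: list with `metrics`, `summary`, `pairwise`
#'   tibbles and bookkeeping (`plan_hash`, `failures`).
#' @export
run_benchmark <- function(dataset, methods, plan, tune = FALSE, grids = NULL,
                          params = NULL, hs_cfg = hs_config(preset = "test"),
                          seed = 1L, verbose = FALSE) {
  if (is.null(dataset$yc)) abort("run prepare_benchmark() first")
  if (!inherits(plan, "cv_plan")) {
    if (is.list(plan) && all(c("reference_ids", "validation_ids") %in% names(plan))) {
      plan <- tibble::tibble(replicate = 1L, fold = 1L,
                             validation_ids = list(plan$validation_ids),
                             reference_ids = list(plan$reference_ids),
                             seed = seed)
      class(plan) <- c("cv_plan", class(plan))
      attr(plan, "plan_hash") <- rlang::hash(plan[c("replicate", "fold", "validation_ids")])
    } else {
      abort("`plan` must be a cv_plan or a forward split")
    }
  }
  method_names <- if (is.list(methods)) names(methods) else methods
  if (is.null(method_names) || any(method_names == "")) {
    abort("methods must be named")
  }
  opts <- list(tune = tune, grids = grids, params = params,
               hs_config = hs_cfg, seed = seed)
  rows <- list()
  preds <- list()
  failures <- list()
  for (i in seq_len(nrow(plan))) {
    ref <- plan$reference_ids[[i]]
    val <- plan$validation_ids[[i]]
    y_val <- dataset$yc$y_c[match(val, dataset$yc$animal)]
    for (m in method_names) {
      spec_m <- if (is.list(methods)) methods[[m]] else m
      pv <- tryCatch(
        benchmark_predict(spec_m, dataset, ref, val, opts),
        error = function(e) {
          failures[[length(failures) + 1L]] <<- tibble::tibble(
            method = m, replicate = plan$replicate[i], fold = plan$fold[i],
            error = conditionMessage(e))
          NULL
        }
      )
      if (is.null(pv)) next
      em <- mse_mae(y_val, pv)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = m, replicate = plan$replicate[i], fold = plan$fold[i],
        n_validation = length(val),
        accuracy = as.numeric(accuracy(y_val, pv)),
        unbiasedness = as.numeric(unbiasedness(y_val, pv)),
        mse = em[["mse"]], mae = em[["mae"]]
      )
      preds[[length(preds) + 1L]] <- tibble::tibble(
        method = m, replicate = plan$replicate[i], animal = val, y_c = y_val,
        pv = pv)
      if (verbose) {
        message(sprintf("replicate %d fold %d %-12s r = %.3f",
                        plan$replicate[i], plan$fold[i], m,
                        rows[[length(rows)]]$accuracy))
      }
    }
  }
  metrics <- dplyr::bind_rows(rows)
  pred_tbl <- dplyr::bind_rows(preds)
  summary <- metrics |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      accuracy_mean = mean(.data$accuracy), accuracy_sd = sd(.data$accuracy),
      unbiasedness_mean = mean(.data$unbiasedness),
      unbiasedness_sd = sd(.data$unbiasedness),
      mse = mean(.data$mse), mae = mean(.data$mae),
      n_folds = dplyr::n(), .groups = "drop"
    )
  pairwise <- benchmark_pairwise(pred_tbl)
  structure(
    list(metrics = metrics, summary = summary, pairwise = pairwise,
         predictions = pred_tbl,
         failures = dplyr::bind_rows(failures),
         plan_hash = attr(plan, "plan_hash")),
    class = "benchmark_result"
  )
}

# Hotelling-Williams comparisons on per-replicate pooled predictions.
benchmark_pairwise <- function(pred_tbl) {
  if (nrow(pred_tbl) == 0L) return(tibble::tibble())
  methods <- unique(pred_tbl$method)
  if (length(methods) < 2L) return(tibble::tibble())
  out <- list()
  for (rep_i in unique(pred_tbl$replicate)) {
    sub <- pred_tbl[pred_tbl$replicate == rep_i, ]
    wide <- tidyr::pivot_wider(sub, id_cols = c("animal", "y_c"),
                               names_from = "method", values_from = "pv")
    for (a_i in seq_along(methods)) {
      for (b_i in seq_along(methods)) {
        if (b_i <= a_i) next
        ma <- methods[a_i]; mb <- methods[b_i]
        pa <- wide[[ma]]; pb <- wide[[mb]]
        keep <- stats::complete.cases(pa, pb, wide$y_c)
        if (sum(keep) <= 3L) next
        r12 <- cor(wide$y_c[keep], pa[keep])
        r13 <- cor(wide$y_c[keep], pb[keep])
        r23 <- cor(pa[keep], pb[keep])
        hw <- if (identical(round(r12, 12), round(r13, 12))) {
          tibble::tibble(t = 0, df = sum(keep) - 3, p_value = 1)
        } else {
          tryCatch(hotelling_williams(r12, r13, min(r23, 1 - 1e-12), sum(keep)),
                   error = function(e) tibble::tibble(t = NA_real_,
                                                      df = NA_real_,
                                                      p_value = NA_real_))
        }
        out[[length(out) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(replicate = rep_i, method_1 = ma, method_2 = mb,
                         r1 = r12, r2 = r13, r_between = r23,
                         n = sum(keep)), hw)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  print(x$summary)
  if (nrow(x$failures)) cat(sprintf("  %d fold failures recorded\n", nrow(x$failures)))
  invisible(x)
}
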