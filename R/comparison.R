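## BIC scoring, model comparison, jackknife resampling, and recovery
## studies.

#' Bayesian information criterion of a fit
#'
#' `BIC = n log(sigma^2) + k log(n)` with the natural logarithm, where
#' `sigma^2` is the fit's mean squared error, `n` the number of fit points
#' and `k` the number of free parameters (4 for the symmetric NB model, 6
#' for WB and CI). Lower is better. A perfect fit (`sigma^2 = 0`, which
#' only happens on noiseless synthetic data) returns `-Inf` with a
#' warning.
#'
#' @param fit a `ci_fit` from [fit_model()], or a number interpreted as
#'   `sigma^2` when `n` and `k` are supplied directly.
#' @param n,k number of fit points and free parameters (only when `fit` is
#'   a bare mean squared error).
#' @return a single number.
#' @examples
#' bic(1, n = 100, k = 4)  # 4 log(100)
#' @export
bic <- function(fit, n = NULL, k = NULL) {
  if (inherits(fit, "ci_fit")) {
    sigma2 <- fit$mse; n <- fit$n; k <- fit$k
  } else {
    sigma2 <- fit
    if (is.null(n) || is.null(k)) {
      stop("supply `n` and `k` when `fit` is a bare mean squared error",
           call. = FALSE)
    }
  }
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  if (sigma2 < 0) stop("`sigma^2` must be non-negative", call. = FALSE)
  if (sigma2 == 0) {
    warning("sigma^2 = 0 (perfect fit); BIC is -Inf", call. = FALSE)
    return(-Inf)
  }
  n * log(sigma2) + k * log(n)
}

#' Compare fitted models by BIC
#'
#' Computes each model's BIC and all pairwise differences with the
#' convention `delta[A, B] = BIC(B) - BIC(A)`, so a positive entry favours
#' model A (row). Differences above 2 are conventionally read as positive
#' evidence and above 6 as strong evidence.
#'
#' @param fits a named list of `ci_fit` objects fitted to the same points.
#' @return an object of class `ci_comparison` with elements `bic` (named
#'   vector), `delta` (matrix), `best` (name of the lowest-BIC model), and
#'   `thresholds`.
#' @export
compare_models <- function(fits) {
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$model, character(1))
  }
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L) {
    stop("fits were not computed on the same number of points: n = ",
         paste(ns, collapse = ", "), call. = FALSE)
  }
  bics <- vapply(fits, bic, numeric(1))
  m <- length(bics)
  delta <- outer(rep(1, m), bics) - outer(bics, rep(1, m))
  dimnames(delta) <- list(names(bics), names(bics))
  structure(list(bic = bics, delta = delta,
                 best = names(bics)[which.min(bics)],
                 thresholds = c(positive = 2, strong = 6)),
            class = "ci_comparison")
}

#' @export
print.ci_comparison <- function(x, ...) {
  cat("<ci_comparison>\nBIC:\n")
  print(round(x$bic, 2))
  cat(sprintf("best model: %s\n", x$best))
  cat("delta BIC (row minus column sign convention: positive favours row):\n")
  print(round(x$delta, 2))
  invisible(x)
}

#' Leave-one-participant-out jackknife of the model comparison
#'
#' Refits every model to each subsample of size N - 1 (one subsample per
#' surviving participant) and recomputes the BIC differences. Subsample
#' refits warm-start at the full-sample optimum and add `n_restarts` fresh
#' random restarts — a documented runtime trade-off; set `n_restarts = 100`
#' for the full protocol. Fit failures are recorded per subsample, never
#' silently dropped.
#'
#' @param points fit points from [to_fit_points()] (all participants).
#' @param models character vector of model ids to compare.
#' @param variant fitting variant shared by all models.
#' @param n_restarts fresh restarts per subsample refit (default 20).
#' @param seed integer seed.
#' @param full_fits optional named list of full-sample `ci_fit` objects to
#'   reuse for warm starts (fitted here if missing).
#' @return an object of class `ci_jackknife`: per-subsample BIC table,
#'   pairwise delta-BIC distributions, counts exceeding the 2 / 4.5 / 6
#'   thresholds, jackknife standard errors, and any failures.
#' @export
jackknife <- function(points, models = model_ids, variant = "symmetric",
                      n_restarts = 20, seed = 1, full_fits = NULL) {
  ids <- unique(points$participant)
  if (length(ids) < 3L) {
    stop("jackknife needs at least 3 participants", call. = FALSE)
  }
  if (is.null(full_fits)) {
    full_fits <- lapply(models, function(m) {
      fit_model(points, m, variant, n_restarts = 100, seed = seed)
    })
    names(full_fits) <- models
  }
  sub_bic <- matrix(NA_real_, length(ids), length(models),
                    dimnames = list(ids, models))
  failures <- list()
  for (i in seq_along(ids)) {
    sub <- dplyr::filter(points, .data$participant != ids[i])
    for (m in models) {
      fit <- tryCatch(
        fit_model(sub, m, variant, n_restarts = n_restarts,
                  seed = seed + i, warm_start = full_fits[[m]]$par),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failures[[length(failures) + 1L]] <-
          tibble::tibble(participant = ids[i], model = m,
                         message = conditionMessage(fit))
      } else {
        sub_bic[i, m] <- bic(fit)
      }
    }
  }
  failures <- if (length(failures)) dplyr::bind_rows(failures) else
    tibble::tibble(participant = character(), model = character(),
                   message = character())

  pairs <- utils::combn(models, 2, simplify = FALSE)
  thresholds <- c(2, 4.5, 6)
  delta <- lapply(pairs, function(pr) sub_bic[, pr[2]] - sub_bic[, pr[1]])
  names(delta) <- vapply(pairs, function(pr)
    paste(pr[1], "vs", pr[2]), character(1))
  n_sub <- length(ids)
  summary <- dplyr::bind_rows(lapply(names(delta), function(nm) {
    d <- delta[[nm]]
    ok <- d[!is.na(d)]
    tibble::tibble(
      pair = nm,
      mean_delta = mean(ok),
      jackknife_se = sqrt((length(ok) - 1) / length(ok) *
                            sum((ok - mean(ok))^2)),
      n_subsamples = n_sub,
      n_exceed_2 = sum(ok > thresholds[1]),
      n_exceed_4.5 = sum(ok > thresholds[2]),
      n_exceed_6 = sum(ok > thresholds[3]))
  }))
  structure(list(bic = sub_bic, delta = delta, summary = summary,
                 thresholds = thresholds, n_subsamples = n_sub,
                 failures = failures, full_fits = full_fits),
            class = "ci_jackknife")
}

#' @export
print.ci_jackknife <- function(x, ...) {
  cat(sprintf("<ci_jackknife> %d leave-one-out subsamples\n",
              x$n_subsamples))
  print(as.data.frame(x$summary))
  if (nrow(x$failures)) {
    cat(sprintf("%d subsample fit(s) failed (see $failures)\n",
                nrow(x$failures)))
  }
  invisible(x)
}

#' Parameter- and model-recovery study on synthetic data
#'
#' For each generating model, repeatedly simulates the full experiment,
#' runs the preprocessing pipeline, fits all candidate models, and records
#' which model wins on BIC together with the error in the recovered
#' parameters of the generating model's own fit.
#'
#' @param generating_models character vector of ground-truth model ids.
#' @param truth a [ci_params()] object used to generate the data.
#' @param n_replicates simulated datasets per generating model.
#' @param group_sizes passed to [build_design()].
#' @param n_restarts restarts per fit.
#' @param seed integer master seed.
#' @return a list with `selection` (one row per replicate and generating
#'   model: BIC winner and per-model BIC) and `recovery` (per-replicate
#'   parameter errors of the matched fit).
#' @export
recovery_study <- function(generating_models = model_ids,
                           truth = default_ground_truth(),
                           n_replicates = 3,
                           group_sizes = c(12, 14, 14, 15),
                           n_restarts = 100, seed = 1) {
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  selection <- list()
  recovery <- list()
  for (g in generating_models) {
    for (r in seq_len(n_replicates)) {
      rep_seed <- seed + 1000L * match(g, model_ids) + r
      design <- build_design(group_sizes, seed = rep_seed)
      trials <- simulate_dataset(design, sim_config(
        model = g, params = truth, seed = rep_seed))
      kept <- exclude_outliers(compute_rp(trials))
      points <- to_fit_points(kept$rp)
      fits <- lapply(model_ids, function(m) {
        fit_model(points, m, n_restarts = n_restarts, seed = rep_seed)
      })
      names(fits) <- model_ids
      cmp <- compare_models(fits)
      selection[[length(selection) + 1L]] <- tibble::tibble(
        generating = g, replicate = r, selected = cmp$best,
        correct = cmp$best == g,
        !!!setNames(as.list(cmp$bic), paste0("bic_", names(cmp$bic))))
      own <- fits[[g]]
      truth_vec <- unlist(unclass(truth)[names(own$par)])
      recovery[[length(recovery) + 1L]] <- tibble::tibble(
        generating = g, replicate = r,
        parameter = names(own$par),
        truth = unname(truth_vec[names(own$par)]),
        estimate = unname(own$par),
        error = unname(own$par) - unname(truth_vec[names(own$par)]))
    }
  }
  list(selection = dplyr::bind_rows(selection),
       recovery = dplyr::bind_rows(recovery))
}
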