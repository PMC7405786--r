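## Constrained multi-start least-squares fitting of the inference models on
## the log-odds scale.

## Free-parameter layout and box bounds per model/variant. Log-odds
## magnitudes are bounded at 10: posterior odds beyond e^10 are
## indistinguishable from certainty at the trial counts this design yields.
free_param_info <- function(model, variant = "symmetric") {
  model <- match.arg(model, model_ids)
  variant <- match.arg(variant, variant_ids)
  nms <- c("L_s_strong", "L_s_weak", "L_impl",
           if (variant == "asymmetric_expl") c("L_expl_SFA", "L_expl_SFB")
           else "L_expl")
  lower <- rep(0, length(nms))
  upper <- rep(10, length(nms))
  if (model %in% c("WB", "CI")) {
    nms <- c(nms, "w_S", "w_P")
    lower <- c(lower, 0.5, 0.5)
    upper <- c(upper, 1, 1)
  }
  if (variant == "softmax") {
    nms <- c(nms, "beta")
    lower <- c(lower, 0.1)
    upper <- c(upper, 10)
  }
  list(names = nms, lower = lower, upper = upper)
}

params_from_vector <- function(v, model, variant) {
  v <- as.list(v)
  asym <- variant == "asymmetric_expl"
  ci_params(
    L_s_strong = v$L_s_strong, L_s_weak = v$L_s_weak, L_impl = v$L_impl,
    L_expl = if (asym) 0 else v$L_expl,
    w_S = if (is.null(v$w_S)) 1 else v$w_S,
    w_P = if (is.null(v$w_P)) 1 else v$w_P,
    beta = if (is.null(v$beta)) 1 else v$beta,
    L_expl_SFA = if (asym) v$L_expl_SFA else NULL,
    L_expl_SFB = if (asym) v$L_expl_SFB else NULL,
    shared_wP = variant == "shared_wP")
}

## Collapse fit points to per-condition sufficient statistics so the
## objective costs O(#cells), not O(#points), per evaluation.
point_cells <- function(points) {
  points |>
    dplyr::group_by(.data$group, .data$cue) |>
    dplyr::summarise(n = dplyr::n(), sum_l = sum(.data$l_rp_obs),
                     sum_l2 = sum(.data$l_rp_obs^2), .groups = "drop")
}

cell_mse <- function(pred, cells) {
  # max(0, .) guards against tiny negative values from cancellation when
  # the fit is essentially perfect
  max(0, sum(cells$sum_l2 - 2 * pred * cells$sum_l + cells$n * pred^2) /
        sum(cells$n))
}

#' Mean squared error of a model on log-odds fit points
#'
#' The fitting objective: the mean over all participants' fit points of
#' the squared distance between the observed log-odds of RP and the model
#' prediction for that point's condition. Every participant's points enter
#' individually (duplicated conditions count once per point), matching a
#' shared-parameter fit across participants.
#'
#' @param params a [ci_params()] object.
#' @param points fit points from [to_fit_points()].
#' @param model one of `"NB"`, `"WB"`, `"CI"`.
#' @param variant one of [variant_ids]; `"softmax"` multiplies predictions
#'   by the decision gain `beta`.
#' @return a single non-negative number.
#' @export
objective <- function(params, points, model, variant = "symmetric") {
  model <- match.arg(model, model_ids)
  variant <- match.arg(variant, variant_ids)
  if (nrow(points) == 0L) stop("no fit points supplied", call. = FALSE)
  cells <- point_cells(points)
  pred <- predict_log_posterior(model, params, cells)
  if (variant == "softmax") pred <- params$beta * pred
  cell_mse(pred, cells)
}

#' Fit a model to log-odds fit points by multi-start constrained
#' least squares
#'
#' Minimises [objective()] with a bound-constrained quasi-Newton optimiser
#' (`optim(method = "L-BFGS-B")`), restarted from `n_restarts` uniform
#' random initialisations within the parameter bounds (log-odds magnitudes
#' in `[0, 10]`, weights in `[0.5, 1]`). The restart initialisations are
#' drawn sequentially from the seed, so increasing `n_restarts` extends,
#' rather than reshuffles, the set of starting points. The best local
#' optimum over all restarts is returned.
#'
#' @param points fit points from [to_fit_points()].
#' @param model one of `"NB"`, `"WB"`, `"CI"`.
#' @param variant one of [variant_ids].
#' @param n_restarts number of random initialisations (default 100).
#' @param seed integer seed controlling the initialisations.
#' @param warm_start optional named numeric vector used as an additional
#'   first initialisation (used by the jackknife to start subsample refits
#'   at the full-sample optimum).
#' @return an object of class `ci_fit`: fitted parameters, `mse`, `n`
#'   (number of fit points), `k` (number of free parameters), the
#'   per-restart best objectives, and convergence information.
#' @export
fit_model <- function(points, model, variant = "symmetric",
                      n_restarts = 100, seed = 1, warm_start = NULL) {
  model <- match.arg(model, model_ids)
  variant <- match.arg(variant, variant_ids)
  if (n_restarts < 1L) stop("`n_restarts` must be >= 1", call. = FALSE)
  if (nrow(points) == 0L) stop("no fit points supplied", call. = FALSE)
  info <- free_param_info(model, variant)
  k <- length(info$names)
  cells <- point_cells(points)

  obj_vec <- function(v) {
    pv <- setNames(v, info$names)
    params <- params_from_vector(pv, model, variant)
    pred <- predict_log_posterior(model, params, cells)
    if (variant == "softmax") pred <- params$beta * pred
    cell_mse(pred, cells)
  }

  set.seed(as.integer(seed))
  inits <- vector("list", n_restarts)
  for (i in seq_len(n_restarts)) {
    inits[[i]] <- info$lower + runif(k) * (info$upper - info$lower)
  }
  if (!is.null(warm_start)) {
    ws <- warm_start[info$names]
    if (any(is.na(ws))) {
      stop("`warm_start` must name every free parameter", call. = FALSE)
    }
    inits <- c(list(pmin(pmax(ws, info$lower), info$upper)), inits)
  }

  restart_obj <- rep(NA_real_, length(inits))
  best <- NULL
  for (i in seq_along(inits)) {
    res <- tryCatch(
      optim(inits[[i]], obj_vec, method = "L-BFGS-B",
            lower = info$lower, upper = info$upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    restart_obj[i] <- res$value
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop(sprintf(
      "all %d restarts failed for model %s (%s); check the fit points",
      length(inits), model, variant), call. = FALSE)
  }

  pv <- setNames(best$par, info$names)
  structure(list(
    model = model, variant = variant,
    par = pv, params = params_from_vector(pv, model, variant),
    mse = best$value, n = nrow(points), k = k,
    n_restarts = n_restarts, restart_objectives = restart_obj,
    converged = best$convergence == 0, seed = as.integer(seed),
    warm_started = !is.null(warm_start)), class = "ci_fit")
}

#' @export
print.ci_fit <- function(x, ...) {
  cat(sprintf("<ci_fit> %s (%s): mse = %.5g over n = %d points, k = %d\n",
              x$model, x$variant, x$mse, x$n, x$k))
  print(round(x$par, 4))
  if (!x$converged) cat("warning: best restart did not report convergence\n")
  invisible(x)
}
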