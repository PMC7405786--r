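## Closed-form posterior models (NB, WB, CI) on the log-odds scale, the
## loopy sigmoid message factor, slopes, and decision rules.

#' Loopy sigmoid message factor
#'
#' The weighted message passed between nodes of the hierarchical generative
#' model: `F(L, w) = log((w e^L + 1 - w) / ((1 - w) e^L + w))`. The factor
#' is odd in `L`, strictly increasing for `w > 0.5`, saturates at
#' `+/- log(w / (1 - w))` for `w < 1`, is identically 0 at the
#' uninformative weight `w = 0.5`, and reduces to the identity at full
#' trust `w = 1`.
#'
#' @param L numeric vector of log-odds; must be finite.
#' @param w numeric vector of weights in `[0, 1]` (recycled against `L`).
#'   In the models only `[0.5, 1]` is used; the formula is defined on the
#'   whole unit interval.
#' @return numeric vector of transformed log-odds.
#' @examples
#' loop_factor(2, 0.8)
#' loop_factor(c(-1, 0, 1), 0.77)
#' @export
loop_factor <- function(L, w) {
  if (!is.numeric(L) || !is.numeric(w)) {
    stop("`L` and `w` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(L))) {
    stop("`L` must be finite", call. = FALSE)
  }
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    stop("`w` must lie in [0, 1]", call. = FALSE)
  }
  eL <- exp(L)
  log((w * eL + 1 - w) / ((1 - w) * eL + w))
}

#' Log-odds (logit) transform and its inverse
#'
#' Natural-log odds of a probability; the scale on which likelihoods,
#' priors and posteriors combine in all three models.
#'
#' @param p probability strictly inside (0, 1). Clipping of empirical
#'   proportions at 0 or 1 is the caller's responsibility (see
#'   [to_fit_points()]).
#' @param L finite log-odds.
#' @return `logit()` returns log-odds; `inv_logit()` returns a probability.
#' @examples
#' logit(0.75) # log 3
#' inv_logit(logit(0.3))
#' @export
logit <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  }
  qlogis(p)
}

#' @rdname logit
#' @export
inv_logit <- function(L) {
  if (!is.numeric(L) || any(is.na(L))) {
    stop("`L` must be numeric and non-missing", call. = FALSE)
  }
  plogis(L)
}

#' Model parameter set
#'
#' Free parameters of the inference models. All log-odds magnitudes are
#' non-negative; the sign with which they enter a given condition is
#' carried by the design (cue orientation, instruction direction), not by
#' the parameter. Weights live in `[0.5, 1]` (0.5 = uninformative, 1 =
#' full trust).
#'
#' @param L_s_strong,L_s_weak sensory log-likelihood magnitudes for the
#'   strong (30% contrast) and weak (20% contrast) shadow cues.
#' @param L_impl implicit prior magnitude (the spontaneous seen-from-above
#'   preference for the upright cube).
#' @param L_expl explicit prior magnitude induced by verbal instructions.
#' @param w_S,w_P trust in the sensory message and in the prior message
#'   (ignored by the NB model).
#' @param beta decision gain of the softmax rule; 1 recovers probability
#'   matching.
#' @param L_expl_SFA,L_expl_SFB optional asymmetric explicit-prior
#'   magnitudes (supporting vs contradicting instructions); when supplied
#'   they replace `L_expl`.
#' @param shared_wP if `TRUE`, the prior weight also applies to the
#'   tilted-cube group; by default that group's `w_P` is pinned to 0.5
#'   because the viewpoint prior is uninformative about a tilted cube.
#' @return an object of class `ci_params` (a validated named list).
#' @examples
#' ci_params(L_s_strong = 1.5, L_s_weak = 0.7, L_impl = 0.5, L_expl = 0.4,
#'           w_S = 0.66, w_P = 0.59)
#' @export
ci_params <- function(L_s_strong = 1, L_s_weak = 0.5, L_impl = 0.5,
                      L_expl = 0.5, w_S = 0.75, w_P = 0.6, beta = 1,
                      L_expl_SFA = NULL, L_expl_SFB = NULL,
                      shared_wP = FALSE) {
  p <- list(L_s_strong = L_s_strong, L_s_weak = L_s_weak,
            L_impl = L_impl, L_expl = L_expl, w_S = w_S, w_P = w_P,
            beta = beta, L_expl_SFA = L_expl_SFA, L_expl_SFB = L_expl_SFB,
            shared_wP = isTRUE(shared_wP))
  validate_ci_params(p)
  structure(p, class = "ci_params")
}

validate_ci_params <- function(p) {
  mags <- c("L_s_strong", "L_s_weak", "L_impl", "L_expl")
  for (nm in mags) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("`%s` must be a single finite non-negative number", nm),
           call. = FALSE)
    }
  }
  for (nm in c("w_S", "w_P")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0.5 || v > 1) {
      stop(sprintf("`%s` must lie in [0.5, 1]", nm), call. = FALSE)
    }
  }
  if (!is.numeric(p$beta) || length(p$beta) != 1L || !is.finite(p$beta) ||
      p$beta <= 0) {
    stop("`beta` must be a single positive number", call. = FALSE)
  }
  asym <- c(p["L_expl_SFA"], p["L_expl_SFB"])
  if (xor(is.null(p$L_expl_SFA), is.null(p$L_expl_SFB))) {
    stop("supply both `L_expl_SFA` and `L_expl_SFB` or neither",
         call. = FALSE)
  }
  for (nm in c("L_expl_SFA", "L_expl_SFB")) {
    v <- p[[nm]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L ||
                        !is.finite(v) || v < 0)) {
      stop(sprintf("`%s` must be a single finite non-negative number", nm),
           call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.ci_params <- function(x, ...) {
  cat("<ci_params>\n")
  num <- vapply(x[c("L_s_strong", "L_s_weak", "L_impl", "L_expl",
                    "w_S", "w_P", "beta")], identity, numeric(1))
  print(round(num, 4))
  if (!is.null(x$L_expl_SFA)) {
    cat(sprintf("asymmetric explicit prior: SFA = %.4g, SFB = %.4g\n",
                x$L_expl_SFA, x$L_expl_SFB))
  }
  if (isTRUE(x$shared_wP)) cat("shared w_P across groups (incl. tilted)\n")
  invisible(x)
}

## Map a (group, cue) design cell to the signed model inputs.
## Orientation convention: SFA is coded as response 1, so supporting cues
## and instructions carry a positive sign and contradicting ones negative.
condition_inputs <- function(params, group, cue) {
  stopifnot(length(group) == length(cue))
  bad_g <- setdiff(unique(group), group_levels)
  if (length(bad_g)) {
    stop("unknown group label(s): ", paste(bad_g, collapse = ", "),
         call. = FALSE)
  }
  bad_c <- setdiff(unique(cue), cue_levels)
  if (length(bad_c)) {
    stop("unknown cue label(s): ", paste(bad_c, collapse = ", "),
         call. = FALSE)
  }
  cue_sign <- c(strong_contra = -1, weak_contra = -1, ambiguous = 0,
                weak_supp = 1, strong_supp = 1)[cue]
  cue_mag <- c(strong_contra = params$L_s_strong,
               weak_contra = params$L_s_weak,
               ambiguous = 0,
               weak_supp = params$L_s_weak,
               strong_supp = params$L_s_strong)[cue]
  L_S <- unname(cue_sign * cue_mag)

  expl_supp <- if (is.null(params$L_expl_SFA)) params$L_expl else params$L_expl_SFA
  expl_contra <- if (is.null(params$L_expl_SFB)) params$L_expl else params$L_expl_SFB
  L_impl_eff <- ifelse(group == "tilted", 0, params$L_impl)
  L_expl_eff <- unname(c(tilted = 0, supporting = expl_supp,
                         contradicting = -expl_contra, none = 0)[group])
  w_P_eff <- ifelse(group == "tilted" & !isTRUE(params$shared_wP),
                    0.5, params$w_P)
  list(L_S = L_S, L_Pr = L_impl_eff + L_expl_eff, w_P = unname(w_P_eff))
}

## Core posterior log-odds for raw inputs; vectorised over L_S / L_Pr / w_P.
model_log_odds <- function(model, L_S, L_Pr, w_S, w_P) {
  switch(model,
    NB = L_S + L_Pr,
    WB = loop_factor(L_S, w_S) + loop_factor(L_Pr, w_P),
    CI = {
      reverb <- loop_factor(L_S, w_S) + loop_factor(L_Pr, w_P)
      loop_factor(L_S + reverb, w_S) + loop_factor(L_Pr + reverb, w_P)
    },
    stop(sprintf("unknown model id '%s' (use one of %s)", model,
                 paste(model_ids, collapse = ", ")), call. = FALSE)
  )
}

#' Posterior log-odds predicted by a model for design conditions
#'
#' Computes the log-odds of reporting the seen-from-above interpretation
#' under the NB, WB, or CI model. NB adds the sensory and prior log-odds;
#' WB passes each through the weighted sigmoid factor; CI additionally
#' feeds the summed messages back into both branches once, so evidence and
#' prior reverberate and are overcounted. For the tilted-cube group the
#' viewpoint prior is uninformative and its weight is pinned at 0.5
#' (unless `shared_wP` is set in `params`), and both prior magnitudes are
#' dropped.
#'
#' @param model one of `"NB"`, `"WB"`, `"CI"`.
#' @param params a [ci_params()] object.
#' @param conditions a data frame with columns `group` and `cue`, or a
#'   single group/cue pair given as `conditions = list(group=, cue=)`.
#' @return numeric vector of posterior log-odds, one per condition row.
#' @examples
#' p <- ci_params(w_S = 0.66, w_P = 0.59)
#' predict_log_posterior("CI", p,
#'   data.frame(group = "contradicting", cue = cue_levels))
#' @export
predict_log_posterior <- function(model, params, conditions) {
  model <- match.arg(model, model_ids)
  validate_ci_params(params)
  if (!all(c("group", "cue") %in% names(conditions))) {
    stop("`conditions` needs `group` and `cue` entries", call. = FALSE)
  }
  inp <- condition_inputs(params, as.character(conditions$group),
                          as.character(conditions$cue))
  model_log_odds(model, inp$L_S, inp$L_Pr, params$w_S, inp$w_P)
}

#' Slope of the posterior log-odds in the sensory log-odds
#'
#' Central finite-difference derivative of the predicted posterior
#' log-odds with respect to the sensory log-likelihood ratio, at a given
#' operating point. Around zero with zero prior the closed forms are 1 for
#' NB, `2 w_S - 1` for WB, and `(2 w_S - 1)(2 w_S + 2 w_P - 1)` for CI;
#' these analytic values are used as test oracles for this routine.
#'
#' @param model one of `"NB"`, `"WB"`, `"CI"`.
#' @param params a [ci_params()] object supplying `w_S` and `w_P`.
#' @param L_prior total prior log-odds at the operating point.
#' @param at_L_S sensory log-odds at which the derivative is taken.
#' @param step finite-difference half-step (default `1e-4`).
#' @return the slope, a single number.
#' @examples
#' slope_at("CI", ci_params(w_S = 0.95, w_P = 0.95), L_prior = 0, at_L_S = 0)
#' @export
slope_at <- function(model, params, L_prior = 0, at_L_S = 0, step = 1e-4) {
  model <- match.arg(model, model_ids)
  validate_ci_params(params)
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) ||
      step <= 0) {
    stop("`step` must be a single positive number", call. = FALSE)
  }
  f <- function(ls) model_log_odds(model, ls, L_prior, params$w_S, params$w_P)
  (f(at_L_S + step) - f(at_L_S - step)) / (2 * step)
}

#' Probability of reporting the seen-from-above percept
#'
#' Maps posterior log-odds to a report probability. Probability matching
#' (the default) reports with probability equal to the posterior; the
#' softmax rule applies a global gain `beta` to the log-odds first, and
#' reduces to matching at `beta = 1`.
#'
#' @param L_RP posterior log-odds (vectorised).
#' @param rule `"matching"` or `"softmax"`.
#' @param beta positive decision gain (softmax only).
#' @return vector of probabilities in (0, 1).
#' @examples
#' response_probability(0)                       # chance
#' response_probability(0.1, "softmax", beta = 50)
#' @export
response_probability <- function(L_RP, rule = c("matching", "softmax"),
                                 beta = 1) {
  rule <- match.arg(rule)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0) {
    stop("`beta` must be a single positive number", call. = FALSE)
  }
  if (rule == "matching") plogis(L_RP) else plogis(beta * L_RP)
}
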