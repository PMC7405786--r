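## From trial records to relative-predominance summaries and log-odds fit
## points, with the participant exclusion rule.

#' Per-participant relative predominance by condition
#'
#' Relative predominance (RP) is the fraction of trials on which the
#' seen-from-above interpretation was reported. The two ambiguous blocks
#' are pooled into a single condition, so every participant contributes
#' exactly five RP values (250 trials for the pooled ambiguous condition
#' and 125 for each cued condition under the default design).
#'
#' @param trials a trial table with columns `participant`, `group`, `cue`,
#'   `response` (binary).
#' @return a tibble with columns `participant`, `group`, `cue`, `rp`,
#'   `n_trials`.
#' @export
compute_rp <- function(trials) {
  req <- c("participant", "group", "cue", "response")
  if (!all(req %in% names(trials))) {
    stop("`trials` is missing columns: ",
         paste(setdiff(req, names(trials)), collapse = ", "), call. = FALSE)
  }
  if (!all(trials$response %in% c(0L, 1L))) {
    stop("`response` must be binary (0/1)", call. = FALSE)
  }
  rp <- trials |>
    dplyr::group_by(.data$participant, .data$group, .data$cue) |>
    dplyr::summarise(rp = mean(.data$response),
                     n_trials = dplyr::n(), .groups = "drop")
  bad <- rp |>
    dplyr::count(.data$participant) |>
    dplyr::filter(.data$n != length(cue_levels))
  if (nrow(bad)) {
    stop("participant(s) missing cue conditions: ",
         paste(bad$participant, collapse = ", "), call. = FALSE)
  }
  rp$cue <- factor(rp$cue, levels = cue_levels)
  dplyr::arrange(rp, .data$participant, .data$cue)
}

#' Exclude participants with outlying mean relative predominance
#'
#' Computes each participant's grand-mean RP over all trials (the
#' trial-count-weighted mean of the condition RPs) and flags participants
#' strictly outside the Tukey fences `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`.
#' Quartiles use linear interpolation with index `(n - 1) q`
#' ([stats::quantile()] type 7). Flagged participants are removed from the
#' returned table.
#'
#' @param rp an RP table from [compute_rp()].
#' @return a list with `rp` (the filtered table) and `flags` (one row per
#'   participant with the mean RP, the fences, and the exclusion flag).
#' @export
exclude_outliers <- function(rp) {
  means <- rp |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      mean_rp = sum(.data$rp * .data$n_trials) / sum(.data$n_trials),
      .groups = "drop")
  if (nrow(means) < 4L) {
    stop("outlier screening needs at least 4 participants (got ",
         nrow(means), "): quartile fences are meaningless below that",
         call. = FALSE)
  }
  q <- quantile(means$mean_rp, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  flags <- means |>
    dplyr::mutate(lower_fence = lo, upper_fence = hi,
                  excluded = .data$mean_rp < lo | .data$mean_rp > hi)
  keep <- flags$participant[!flags$excluded]
  list(rp = dplyr::filter(rp, .data$participant %in% keep), flags = flags)
}

#' Report-only qualitative screening flags
#'
#' Mirrors the qualitative checks used to describe excluded participants
#' (cue effects in the wrong direction, flat curves at or below chance,
#' RP pinned near 0 or 1 in the ambiguous condition). Thresholds for these
#' descriptions are not quantified anywhere, so the flags are informative
#' only and never remove anyone.
#'
#' @param rp an RP table from [compute_rp()].
#' @param extreme_margin RP within this distance of 0 or 1 in the ambiguous
#'   condition counts as extreme (default 0.02).
#' @return a tibble with one row per participant and logical columns
#'   `negative_slope`, `flat_curve`, `extreme_ambiguous`.
#' @export
flag_qualitative <- function(rp, extreme_margin = 0.02) {
  rp |>
    dplyr::group_by(.data$participant, .data$group) |>
    dplyr::summarise(
      negative_slope = stats::cor(as.integer(.data$cue), .data$rp,
                                  method = "spearman") < 0,
      flat_curve = all(.data$rp <= 0.5) &&
        (max(.data$rp) - min(.data$rp)) < 0.05,
      extreme_ambiguous = any(.data$cue == "ambiguous" &
        (.data$rp <= extreme_margin | .data$rp >= 1 - extreme_margin)),
      .groups = "drop")
}

#' Log-odds fit points from an RP table
#'
#' Applies the empirical-logit correction before the log-odds transform:
#' RP is clipped to `[eps, 1 - eps]` with `eps = 1 / (2 n_trials)`, so a
#' participant at RP = 1 over 125 trials maps to log(249) rather than
#' infinity. The transform is monotone in RP.
#'
#' @param rp an RP table from [compute_rp()].
#' @return a tibble with columns `participant`, `group`, `cue`,
#'   `l_rp_obs`, `n_trials`.
#' @export
to_fit_points <- function(rp) {
  if (any(rp$n_trials <= 0)) {
    stop("`n_trials` must be positive for every condition", call. = FALSE)
  }
  eps <- 1 / (2 * rp$n_trials)
  clipped <- pmin(pmax(rp$rp, eps), 1 - eps)
  tibble::tibble(participant = rp$participant, group = rp$group,
                 cue = rp$cue, l_rp_obs = qlogis(clipped),
                 n_trials = rp$n_trials)
}
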