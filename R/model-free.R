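## Descriptive summaries and light diagnostics: group RP curves, the
## RP-vs-chance signed-rank check, and within-run response autocorrelation.

#' Average relative-predominance curves per group
#'
#' Mean RP and its standard error across participants for every
#' (group, cue) cell — the descriptive curves usually plotted with cue
#' condition on the x axis, one curve per instruction group.
#'
#' @param rp an RP table from [compute_rp()].
#' @return a tibble with columns `group`, `cue`, `mean_rp`, `se`,
#'   `n_participants`. Groups absent from the table are omitted with a
#'   warning.
#' @export
group_curves <- function(rp) {
  if (nrow(rp) == 0L) stop("empty RP table", call. = FALSE)
  missing_groups <- setdiff(group_levels, unique(as.character(rp$group)))
  if (length(missing_groups)) {
    warning("no participants in group(s): ",
            paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  rp |>
    dplyr::group_by(.data$group, .data$cue) |>
    dplyr::summarise(
      mean_rp = mean(.data$rp),
      se = if (dplyr::n() > 1L) sd(.data$rp) / sqrt(dplyr::n()) else 0,
      n_participants = dplyr::n(), .groups = "drop")
}

#' Test relative predominance against chance
#'
#' One-sample two-tailed Wilcoxon signed-rank test of a set of RP values
#' against 0.5 (delegated to [stats::wilcox.test()]). With every value
#' exactly at chance the test is degenerate and reported as such rather
#' than run.
#'
#' @param values numeric vector of RP values (at least 5).
#' @return a list with `statistic`, `p_value`, `n`, `median`, and
#'   `degenerate`.
#' @export
rp_vs_chance <- function(values) {
  if (!is.numeric(values) || length(values) < 5L) {
    stop("need at least 5 RP values", call. = FALSE)
  }
  if (all(values == 0.5)) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                n = length(values), median = 0.5, degenerate = TRUE))
  }
  wt <- suppressWarnings(wilcox.test(values, mu = 0.5, exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = length(values), median = stats::median(values),
       degenerate = FALSE)
}

#' Within-run autocorrelation of response sequences
#'
#' Sample autocorrelation of the binary response sequence at lags 1..
#' `max_lag`, computed within each run (sequences never cross run
#' boundaries) and averaged across runs and participants. Runs with zero
#' response variance have undefined autocorrelation and are counted as
#' missing. Under the independence assumption of the models the lag-1
#' estimate is near 0; response persistence shows up as positive values.
#'
#' @param trials a trial table with columns `participant`, `block`, `run`,
#'   `trial`, `response`.
#' @param max_lag largest lag, strictly less than the run length.
#' @return a tibble with columns `lag`, `acf` (mean across defined runs),
#'   `n_runs` (runs contributing at that lag).
#' @export
autocorrelation <- function(trials, max_lag = 5) {
  req <- c("participant", "block", "run", "trial", "response")
  if (!all(req %in% names(trials))) {
    stop("`trials` is missing columns: ",
         paste(setdiff(req, names(trials)), collapse = ", "), call. = FALSE)
  }
  run_len <- min(table(interaction(trials$participant, trials$block,
                                   trials$run, drop = TRUE)))
  if (max_lag < 1L || max_lag >= run_len) {
    stop(sprintf("`max_lag` must be in [1, %d) for runs of %d trials",
                 run_len, run_len), call. = FALSE)
  }
  runs <- split(trials$response[order(trials$participant, trials$block,
                                      trials$run, trials$trial)],
                interaction(trials$participant, trials$block, trials$run,
                            drop = TRUE)[order(trials$participant,
                                               trials$block, trials$run,
                                               trials$trial)])
  per_run <- vapply(runs, function(x) {
    x <- as.numeric(x)
    v <- sum((x - mean(x))^2)
    if (v == 0) return(rep(NA_real_, max_lag))
    vapply(seq_len(max_lag), function(k) {
      n <- length(x)
      sum((x[1:(n - k)] - mean(x)) * (x[(k + 1):n] - mean(x))) / v
    }, numeric(1))
  }, numeric(max_lag))
  per_run <- matrix(per_run, nrow = max_lag)
  tibble::tibble(
    lag = seq_len(max_lag),
    acf = rowMeans(per_run, na.rm = TRUE),
    n_runs = rowSums(!is.na(per_run)))
}
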