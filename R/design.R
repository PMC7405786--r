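## Synthetic experiment: the 4-group between-subjects design and trial-level
## response generation from a ground-truth model.

#' Build the experimental design table
#'
#' One row per sound trial. Each participant completes 6 blocks of 5 runs
#' of 25 trials (750 rows). Blocks 1 and 4 always present the ambiguous
#' cube; the four cue conditions (weak/strong x supporting/contradicting)
#' are assigned to blocks 2, 3, 5, 6 by an independent random permutation
#' per participant. The four groups differ only in the instruction/stimulus
#' manipulation of the prior: tilted cube, supporting instructions,
#' contradicting instructions, or no instructions.
#'
#' @param group_sizes integer vector of length 4: participants per group in
#'   the order tilted, supporting, contradicting, none. Defaults to the
#'   study sizes (12, 14, 14, 15).
#' @param seed integer seed; the table is deterministic given the seed.
#' @return a tibble with columns `participant`, `group`, `block`, `run`,
#'   `trial`, `cue`.
#' @examples
#' d <- build_design(c(2, 2, 2, 2), seed = 1)
#' nrow(d) / 8   # 750 trials per participant
#' @export
build_design <- function(group_sizes = c(12, 14, 14, 15), seed = 1) {
  if (length(group_sizes) != 4L || any(group_sizes != round(group_sizes)) ||
      any(group_sizes <= 0)) {
    stop("`group_sizes` must be four positive integers", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_total <- sum(group_sizes)
  ids <- sprintf("S%02d", seq_len(n_total))
  groups <- rep(group_levels, times = group_sizes)
  cue_blocks <- c(2L, 3L, 5L, 6L)
  cued <- setdiff(cue_levels, "ambiguous")

  per_participant <- lapply(seq_len(n_total), function(i) {
    block_cue <- character(6)
    block_cue[c(1L, 4L)] <- "ambiguous"
    block_cue[cue_blocks] <- sample(cued)
    tibble::tibble(
      participant = ids[i],
      group = groups[i],
      block = rep(1:6, each = 5L * 25L),
      run = rep(rep(1:5, each = 25L), times = 6L),
      trial = rep(1:25, times = 30L),
      cue = block_cue[rep(1:6, each = 5L * 25L)]
    )
  })
  dplyr::bind_rows(per_participant)
}

#' Ground-truth parameters used by the default simulation
#'
#' Weights are set to the circular-inference values a healthy adult sample
#' shows in this task (`w_S = 0.66`, `w_P = 0.59`). The log-odds
#' magnitudes are calibrated so the simulated group curves reproduce the
#' effect sizes observed in such experiments: under this ground truth the
#' tilted-ambiguous RP sits at chance, the implicit prior raises the
#' no-instruction ambiguous RP to about 0.60, contradicting instructions
#' lower RP by about 0.10, supporting instructions barely move it (the
#' prior branch is saturated), and the strong-cue contrast spans about
#' 0.30 in RP — close to the ceiling these weights allow.
#'
#' @return a [ci_params()] object.
#' @export
default_ground_truth <- function() {
  ci_params(L_s_strong = 2.74, L_s_weak = 0.80, L_impl = 2.5, L_expl = 2.4,
            w_S = 0.66, w_P = 0.59)
}

#' Simulation configuration
#'
#' @param model ground-truth model id (`"NB"`, `"WB"`, `"CI"`).
#' @param params a [ci_params()] object with the generating parameters.
#' @param rule decision rule, `"matching"` (default) or `"softmax"`.
#' @param beta softmax gain (ignored under matching).
#' @param heterogeneity_sd standard deviation of centred Gaussian jitter
#'   added to each participant's log-odds magnitudes (truncated at 0);
#'   0 (default) gives identical participants. Weights are never jittered,
#'   so the weight constraints stay intact.
#' @param persistence_rho probability in `[0, 1)` that a trial simply
#'   repeats the previous response within a run instead of being drawn
#'   afresh; 0 (default) reproduces the independence assumption of the
#'   models.
#' @param seed integer master seed; one RNG substream per participant is
#'   derived from it, so datasets are reproducible participant by
#'   participant.
#' @return an object of class `ci_sim_config`.
#' @export
sim_config <- function(model = "CI", params = default_ground_truth(),
                       rule = c("matching", "softmax"), beta = 1,
                       heterogeneity_sd = 0, persistence_rho = 0, seed = 1) {
  model <- match.arg(model, model_ids)
  rule <- match.arg(rule)
  validate_ci_params(params)
  if (!is.numeric(heterogeneity_sd) || heterogeneity_sd < 0) {
    stop("`heterogeneity_sd` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(persistence_rho) || persistence_rho < 0 ||
      persistence_rho >= 1) {
    stop("`persistence_rho` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(model = model, params = params, rule = rule, beta = beta,
                 heterogeneity_sd = heterogeneity_sd,
                 persistence_rho = persistence_rho,
                 seed = as.integer(seed)),
            class = "ci_sim_config")
}

## Jitter one participant's log-odds magnitudes; weights untouched.
jitter_params <- function(params, sd) {
  if (sd == 0) return(params)
  p <- unclass(params)
  for (nm in c("L_s_strong", "L_s_weak", "L_impl", "L_expl")) {
    p[[nm]] <- max(0, p[[nm]] + rnorm(1, 0, sd))
  }
  for (nm in c("L_expl_SFA", "L_expl_SFB")) {
    if (!is.null(p[[nm]])) p[[nm]] <- max(0, p[[nm]] + rnorm(1, 0, sd))
  }
  structure(p, class = "ci_params")
}

#' Simulate trial-level binary responses from a ground-truth model
#'
#' Each response (1 = seen-from-above, 0 = seen-from-below) is drawn with
#' success probability given by the ground-truth model's posterior for the
#' trial's condition, via the configured decision rule. With
#' `persistence_rho > 0` a trial repeats the previous response within the
#' same run with that probability; the first trial of every run is always a
#' fresh draw.
#'
#' @param design a design table from [build_design()].
#' @param cfg a [sim_config()] object.
#' @return the design tibble with an added binary `response` column.
#' @examples
#' d <- build_design(c(1, 1, 1, 1), seed = 1)
#' trials <- simulate_dataset(d, sim_config(seed = 42))
#' mean(trials$response)
#' @export
simulate_dataset <- function(design, cfg) {
  if (!inherits(cfg, "ci_sim_config")) {
    stop("`cfg` must come from sim_config()", call. = FALSE)
  }
  req <- c("participant", "group", "block", "run", "trial", "cue")
  if (!all(req %in% names(design))) {
    stop("`design` is missing columns: ",
         paste(setdiff(req, names(design)), collapse = ", "), call. = FALSE)
  }
  ids <- unique(design$participant)
  set.seed(cfg$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(ids))

  out <- lapply(seq_along(ids), function(i) {
    d <- design[design$participant == ids[i], , drop = FALSE]
    d <- d[order(d$block, d$run, d$trial), , drop = FALSE]
    set.seed(sub_seeds[i])
    pars <- jitter_params(cfg$params, cfg$heterogeneity_sd)
    cell <- unique(d[, c("group", "cue")])
    lrp <- predict_log_posterior(cfg$model, pars, cell)
    cell$p <- response_probability(lrp, cfg$rule, cfg$beta)
    p_row <- cell$p[match(d$cue, cell$cue)]
    if (cfg$persistence_rho == 0) {
      d$response <- rbinom(nrow(d), 1L, p_row)
    } else {
      d$response <- NA_integer_
      run_id <- interaction(d$block, d$run, drop = TRUE)
      for (r in levels(run_id)) {
        idx <- which(run_id == r)
        fresh <- rbinom(length(idx), 1L, p_row[idx])
        carry <- runif(length(idx)) < cfg$persistence_rho
        resp <- fresh
        for (t in seq_along(idx)[-1]) {
          if (carry[t]) resp[t] <- resp[t - 1L]
        }
        d$response[idx] <- resp
      }
    }
    d
  })
  dplyr::bind_rows(out)
}
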