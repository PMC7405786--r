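## End-to-end pipeline: configuration, IO, and report generation.

#' Pipeline configuration
#'
#' Assembles (and validates) the configuration consumed by
#' [run_pipeline()]. Every random procedure takes its seed from here.
#'
#' @param simulation a [sim_config()] object, or `NULL` when `trials_file`
#'   is given.
#' @param trials_file optional path to an existing trial table (tab
#'   separated with header participant/group/block/run/trial/cue/response);
#'   when set, simulation is skipped.
#' @param group_sizes participants per group for the simulated design.
#' @param exclude_outliers logical; apply the Tukey-fence screening.
#' @param models model ids to fit.
#' @param variant fitting variant.
#' @param n_restarts restarts per full-sample fit.
#' @param run_jackknife logical; leave-one-out model comparison.
#' @param jackknife_restarts fresh restarts per jackknife refit.
#' @param seed master seed for fitting (simulation uses its own seed).
#' @return an object of class `ci_pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            trials_file = NULL,
                            group_sizes = c(12, 14, 14, 15),
                            exclude_outliers = TRUE,
                            models = model_ids,
                            variant = "symmetric",
                            n_restarts = 100,
                            run_jackknife = FALSE,
                            jackknife_restarts = 20,
                            seed = 1) {
  if (is.null(trials_file) && !inherits(simulation, "ci_sim_config")) {
    stop("supply either a sim_config() or a `trials_file`", call. = FALSE)
  }
  models <- match.arg(models, model_ids, several.ok = TRUE)
  variant <- match.arg(variant, variant_ids)
  structure(list(simulation = simulation, trials_file = trials_file,
                 group_sizes = group_sizes,
                 exclude_outliers = isTRUE(exclude_outliers),
                 models = models, variant = variant,
                 n_restarts = n_restarts,
                 run_jackknife = isTRUE(run_jackknife),
                 jackknife_restarts = jackknife_restarts,
                 seed = as.integer(seed)),
            class = "ci_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised top-level keys mirror the arguments of [pipeline_config()];
#' the `simulation` block mirrors [sim_config()] with a nested `params`
#' block for [ci_params()].
#'
#' @param path YAML file path.
#' @return a `ci_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (is.null(y$trials_file)) {
    s <- y$simulation %||% list()
    pars <- do.call(ci_params, s$params %||% list())
    sim <- sim_config(model = s$model %||% "CI", params = pars,
                      rule = s$rule %||% "matching",
                      beta = s$beta %||% 1,
                      heterogeneity_sd = s$heterogeneity_sd %||% 0,
                      persistence_rho = s$persistence_rho %||% 0,
                      seed = s$seed %||% 1)
  }
  args <- y[setdiff(names(y), "simulation")]
  do.call(pipeline_config, c(list(simulation = sim), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a trial table
#'
#' @param path tab-separated file with header columns `participant`,
#'   `group`, `block`, `run`, `trial`, `cue`, `response`.
#' @return a validated tibble of trial records.
#' @export
load_trials <- function(path) {
  tr <- tibble::as_tibble(read.delim(path, sep = "\t",
                                     stringsAsFactors = FALSE))
  req <- c("participant", "group", "block", "run", "trial", "cue",
           "response")
  miss <- setdiff(req, names(tr))
  if (length(miss)) {
    stop("trial table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!(tr$response %in% c(0L, 1L)))
  if (length(bad)) {
    stop("non-binary response values at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  bad <- which(!(tr$cue %in% cue_levels))
  if (length(bad)) {
    stop("unknown cue label(s) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  bad <- which(!(tr$group %in% group_levels))
  if (length(bad)) {
    stop("unknown group label(s) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  tr
}

#' Write a trial table
#'
#' @param trials a trial tibble.
#' @param path output path (tab separated, header, no quoting).
#' @export
write_trials <- function(trials, path) {
  write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv_ <- function(df, path) {
  df <- as.data.frame(df)
  df[] <- lapply(df, function(x) if (is.factor(x)) as.character(x) else x)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fit_to_list <- function(f) {
  list(model = f$model, variant = f$variant, par = as.list(f$par),
       mse = f$mse, n = f$n, k = f$k, bic = bic(f),
       n_restarts = f$n_restarts, converged = f$converged, seed = f$seed)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) trials, summarise relative predominance, screen
#' outliers, fit the requested models, compare them by BIC, and optionally
#' jackknife the comparison. Every intermediate table and a machine-
#' readable report are written to `out_dir`; the run log records seeds,
#' counts and a hash of the configuration, so identical configurations
#' yield identical outputs.
#'
#' @param config a [pipeline_config()] object (or path to a YAML file).
#' @param out_dir output directory, created if needed.
#' @return (invisibly) a list with `trials`, `rp`, `flags`, `points`,
#'   `curves`, `fits`, `comparison`, and (if requested) `jackknife`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "ci_pipeline_config")) {
    stop("`config` must come from pipeline_config()", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  cfg_hash <- rlang::hash(unclass(config))
  yaml::write_yaml(list(config_hash = cfg_hash,
                        seed = config$seed,
                        models = config$models,
                        variant = config$variant),
                   file.path(out_dir, "config.yaml"))
  logf("config hash %s", cfg_hash)

  stage <- "simulate"
  res <- tryCatch({
    if (!is.null(config$trials_file)) {
      logf("loading trials from %s", config$trials_file)
      trials <- load_trials(config$trials_file)
    } else {
      logf("simulating %s ground truth, seed %d (groups: %s)",
           config$simulation$model, config$simulation$seed,
           paste(config$group_sizes, collapse = "/"))
      design <- build_design(config$group_sizes,
                             seed = config$simulation$seed)
      trials <- simulate_dataset(design, config$simulation)
    }
    write_tsv_(trials, file.path(out_dir, "trials.tsv"))
    logf("%d trials, %d participants", nrow(trials),
         length(unique(trials$participant)))

    stage <- "preprocess"
    rp <- compute_rp(trials)
    flags <- NULL
    if (config$exclude_outliers) {
      scr <- exclude_outliers(rp)
      rp <- scr$rp
      flags <- scr$flags
      write_tsv_(flags, file.path(out_dir, "outlier_flags.tsv"))
      logf("outlier screening: %d excluded, %d kept",
           sum(flags$excluded), sum(!flags$excluded))
    }
    write_tsv_(rp, file.path(out_dir, "rp.tsv"))
    points <- to_fit_points(rp)
    write_tsv_(points, file.path(out_dir, "fit_points.tsv"))
    curves <- group_curves(rp)
    write_tsv_(curves, file.path(out_dir, "group_curves.tsv"))

    stage <- "fit"
    fits <- lapply(config$models, function(m) {
      logf("fitting %s (%s), %d restarts, seed %d", m, config$variant,
           config$n_restarts, config$seed)
      fit_model(points, m, config$variant,
                n_restarts = config$n_restarts, seed = config$seed)
    })
    names(fits) <- config$models
    jsonlite::write_json(lapply(fits, fit_to_list),
                         file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    stage <- "compare"
    comparison <- NULL
    if (length(fits) > 1L) {
      comparison <- compare_models(fits)
      jsonlite::write_json(
        list(bic = as.list(comparison$bic),
             delta = as.data.frame(comparison$delta),
             best = comparison$best),
        file.path(out_dir, "comparison.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      logf("best model by BIC: %s", comparison$best)
    }

    stage <- "jackknife"
    jk <- NULL
    if (config$run_jackknife && length(fits) > 1L) {
      logf("jackknife over %d participants", length(unique(points$participant)))
      jk <- jackknife(points, config$models, config$variant,
                      n_restarts = config$jackknife_restarts,
                      seed = config$seed, full_fits = fits)
      write_tsv_(cbind(participant = rownames(jk$bic),
                       as.data.frame(jk$bic)),
                 file.path(out_dir, "jackknife_bic.tsv"))
      write_tsv_(jk$summary, file.path(out_dir, "jackknife_summary.tsv"))
    }
    list(trials = trials, rp = rp, flags = flags, points = points,
         curves = curves, fits = fits, comparison = comparison,
         jackknife = jk, config_hash = cfg_hash)
  }, error = function(e) {
    logf("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s (partial outputs in %s)",
                 stage, conditionMessage(e), out_dir), call. = FALSE)
  })
  logf("pipeline complete")
  invisible(res)
}
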