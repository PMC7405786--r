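# Shared fixture builders. Everything is generated in code at test time.

# The full (group x cue) condition grid.
condition_grid <- function() {
  expand.grid(group = group_levels, cue = cue_levels,
              stringsAsFactors = FALSE)
}

# Noiseless fit points: one participant per group, l_rp_obs set exactly to
# the model prediction. Exact identification material for the optimiser.
noiseless_points <- function(model, params, n_trials = 125) {
  grid <- condition_grid()
  tibble::tibble(
    participant = paste0("G_", grid$group),
    group = grid$group, cue = grid$cue,
    l_rp_obs = predict_log_posterior(model, params, grid),
    n_trials = n_trials)
}

# A small simulated experiment (2 participants per group by default).
small_experiment <- function(model = "CI", params = default_ground_truth(),
                             per_group = 2, seed = 7, ...) {
  design <- build_design(rep(per_group, 4), seed = seed)
  simulate_dataset(design, sim_config(model = model, params = params,
                                      seed = seed, ...))
}

# NB design matrix for the closed-form least-squares oracle.
nb_design_matrix <- function(points) {
  sgn <- c(strong_contra = -1, weak_contra = -1, ambiguous = 0,
           weak_supp = 1, strong_supp = 1)[as.character(points$cue)]
  strong <- as.character(points$cue) %in% c("strong_contra", "strong_supp")
  cbind(
    L_s_strong = ifelse(strong, sgn, 0),
    L_s_weak = ifelse(!strong & sgn != 0, sgn, 0),
    L_impl = as.numeric(points$group != "tilted"),
    L_expl = c(tilted = 0, supporting = 1, contradicting = -1,
               none = 0)[as.character(points$group)])
}
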