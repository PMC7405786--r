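# Multi-start constrained least-squares fitting.

test_that("objective is the mean squared log-odds distance", {
  truth <- ci_params(L_s_strong = 1.2, L_s_weak = 0.5, L_impl = 0.6,
                     L_expl = 0.3)
  pts <- noiseless_points("NB", truth)
  expect_equal(objective(truth, pts, "NB"), 0)
  # any perturbation can only increase a noiseless objective
  for (d in c(0.1, -0.05, 0.3)) {
    pert <- truth; pert$L_impl <- max(0, truth$L_impl + d)
    expect_gte(objective(pert, pts, "NB"), 0)
    expect_gt(objective(pert, pts, "NB"), 1e-6)
  }
  # mean semantics: duplicating every point leaves the objective unchanged,
  # and duplicating a single point shifts the weighting
  expect_equal(objective(truth, dplyr::bind_rows(pts, pts), "NB"), 0)
  off <- ci_params(L_s_strong = 2, L_s_weak = 0.5, L_impl = 0.6,
                   L_expl = 0.3)
  one_extra <- dplyr::bind_rows(pts, pts[1, ])
  resid2 <- (pts$l_rp_obs - predict_log_posterior("NB", off, pts))^2
  expect_equal(objective(off, one_extra, "NB"),
               (sum(resid2) + resid2[1]) / (nrow(pts) + 1))
  expect_error(objective(truth, pts[0, ], "NB"), "no fit points")
})

test_that("noiseless NB points are recovered exactly", {
  truth <- ci_params(L_s_strong = 1.4, L_s_weak = 0.6, L_impl = 0.8,
                     L_expl = 0.35)
  pts <- noiseless_points("NB", truth)
  fit <- fit_model(pts, "NB", n_restarts = 10, seed = 2)
  expect_equal(unname(fit$par),
               c(1.4, 0.6, 0.8, 0.35), tolerance = 1e-4)
  expect_lt(fit$mse, 1e-9)
  expect_equal(fit$k, 4)
  expect_true(fit$converged)
})

test_that("noiseless WB and CI points recover the identifiable quantities", {
  truth <- ci_params(L_s_strong = 2.0, L_s_weak = 0.8, L_impl = 1.5,
                     L_expl = 1.2, w_S = 0.7, w_P = 0.62)
  # WB: the sensory branch enters only through the two weighted messages
  # F(L_s_strong, w_S) and F(L_s_weak, w_S), so (w_S, L_s_strong, L_s_weak)
  # trade off along a ridge; the weighted messages themselves and the prior
  # branch are identified
  pts <- noiseless_points("WB", truth)
  fit <- fit_model(pts, "WB", n_restarts = 30, seed = 4)
  expect_lt(fit$mse, 1e-8)
  expect_equal(fit$k, 6)
  expect_equal(loop_factor(fit$par["L_s_strong"], fit$par["w_S"]),
               loop_factor(2.0, 0.7), tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(loop_factor(fit$par["L_s_weak"], fit$par["w_S"]),
               loop_factor(0.8, 0.7), tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(unname(fit$par["w_P"]), 0.62, tolerance = 1e-2)
  # CI: reverberation couples the branches and restores identifiability of
  # both weights
  pts <- noiseless_points("CI", truth)
  fit <- fit_model(pts, "CI", n_restarts = 30, seed = 4)
  expect_lt(fit$mse, 1e-8)
  expect_equal(unname(fit$par[c("w_S", "w_P")]), c(0.7, 0.62),
               tolerance = 1e-2)
})

test_that("the symmetric NB fit matches ordinary least squares", {
  # independent oracle: NB is linear in its parameters, so the constrained
  # multi-start fit must agree with lm() whenever the optimum is interior
  truth <- ci_params(L_s_strong = 1.5, L_s_weak = 0.7, L_impl = 0.9,
                     L_expl = 0.5)
  pts <- noiseless_points("NB", truth)
  set.seed(31)
  pts$l_rp_obs <- pts$l_rp_obs + rnorm(nrow(pts), sd = 0.1)
  X <- nb_design_matrix(pts)
  ols <- coef(lm(pts$l_rp_obs ~ 0 + X))
  fit <- fit_model(pts, "NB", n_restarts = 20, seed = 5)
  expect_equal(unname(fit$par), unname(ols), tolerance = 1e-4)
  expect_equal(fit$mse, mean(residuals(lm(pts$l_rp_obs ~ 0 + X))^2),
               tolerance = 1e-8)
})

test_that("fits are deterministic and restarts only improve the optimum", {
  trials <- small_experiment(seed = 21)
  pts <- to_fit_points(compute_rp(trials))
  f1 <- fit_model(pts, "CI", n_restarts = 8, seed = 9)
  f2 <- fit_model(pts, "CI", n_restarts = 8, seed = 9)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$mse, f2$mse)
  # nested initialisation streams: more restarts never worsen the best
  f_more <- fit_model(pts, "CI", n_restarts = 16, seed = 9)
  expect_lte(f_more$mse, f1$mse)
  expect_equal(f_more$restart_objectives[1:8], f1$restart_objectives)
})

test_that("variants change the free-parameter count as declared", {
  expect_length(circinf:::free_param_info("NB", "symmetric")$names, 4)
  expect_length(circinf:::free_param_info("WB", "symmetric")$names, 6)
  expect_length(circinf:::free_param_info("CI", "symmetric")$names, 6)
  expect_length(circinf:::free_param_info("CI", "asymmetric_expl")$names, 7)
  expect_length(circinf:::free_param_info("CI", "softmax")$names, 7)
  expect_length(circinf:::free_param_info("CI", "shared_wP")$names, 6)
})

test_that("warm starts are honoured and bounds are enforced", {
  truth <- ci_params(L_s_strong = 1.4, L_s_weak = 0.6, L_impl = 0.8,
                     L_expl = 0.35)
  pts <- noiseless_points("NB", truth)
  ws <- c(L_s_strong = 1.4, L_s_weak = 0.6, L_impl = 0.8, L_expl = 0.35)
  fit <- fit_model(pts, "NB", n_restarts = 1, seed = 1, warm_start = ws)
  expect_lt(fit$mse, 1e-10)
  expect_true(fit$warm_started)
  expect_error(fit_model(pts, "NB", warm_start = c(bogus = 1)),
               "every free parameter")
  # fitted parameters always respect the box constraints
  trials <- small_experiment(seed = 33)
  f <- fit_model(to_fit_points(compute_rp(trials)), "CI",
                 n_restarts = 5, seed = 3)
  info <- circinf:::free_param_info("CI", "symmetric")
  expect_true(all(f$par >= info$lower - 1e-12))
  expect_true(all(f$par <= info$upper + 1e-12))
})
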