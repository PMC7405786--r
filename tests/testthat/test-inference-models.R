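# The loopy sigmoid factor, log-odds transforms, model predictions,
# slopes, and decision rules.

test_that("loop factor matches direct evaluation and limiting weights", {
  # 0.9869155064 computed independently by arbitrary-precision evaluation
  # of log((w e^L + 1-w)/((1-w) e^L + w)) at 50 digits
  expect_equal(loop_factor(2, 0.8), 0.9869155064, tolerance = 1e-9)
  expect_identical(loop_factor(0, 0.77), 0)
  expect_equal(loop_factor(3.7, 0.5), 0)          # uninformative weight
  expect_equal(loop_factor(2, 1), 2)              # full trust = identity
  expect_error(loop_factor(Inf, 0.8), "finite")
  expect_error(loop_factor(1, 1.2), "\\[0, 1\\]")
})

test_that("loop factor is odd, monotone, and bounded by the trust odds", {
  L <- seq(-6, 6, by = 0.25)
  for (w in c(0.55, 0.66, 0.77, 0.9, 0.99)) {
    expect_equal(loop_factor(-L, w), -loop_factor(L, w))
    expect_true(all(diff(loop_factor(L, w)) > 0))
    expect_true(all(abs(loop_factor(L, w)) <= log(w / (1 - w)) + 1e-12))
  }
})

test_that("logit and inverse logit are mutual inverses with domain checks", {
  expect_equal(logit(0.5), 0)
  expect_equal(logit(0.75), log(3))
  for (p in c(0.1, 0.3, 0.9)) expect_equal(inv_logit(logit(p)), p)
  expect_error(logit(0), "inside")
  expect_error(logit(1.1), "inside")
})

test_that("model predictions follow their closed forms", {
  # NB: plain sum of signed log-odds (supporting group: +L_expl)
  p <- ci_params(L_s_strong = 1, L_s_weak = 1, L_impl = 0.5, L_expl = 0.2)
  expect_equal(
    predict_log_posterior("NB", p,
                          list(group = "contradicting", cue = "strong_supp")),
    1 + 0.5 - 0.2)
  # CI with unit weights and zero priors triples the sensory input
  p1 <- ci_params(L_s_strong = 0.4, L_s_weak = 0, L_impl = 0, L_expl = 0,
                  w_S = 1, w_P = 1)
  expect_equal(
    predict_log_posterior("CI", p1, list(group = "none", cue = "strong_supp")),
    3 * 0.4)
  # WB at L_S = 1, L_Pr = 0.5, w_S = 0.77, w_P = 0.59: value frozen from an
  # independent arbitrary-precision evaluation of the two-factor sum
  pw <- ci_params(L_s_strong = 1, L_s_weak = 0, L_impl = 0.5, L_expl = 0,
                  w_S = 0.77, w_P = 0.59)
  expect_equal(
    predict_log_posterior("WB", pw, list(group = "none", cue = "strong_supp")),
    0.5980792798, tolerance = 1e-9)
  expect_error(circinf:::model_log_odds("XX", 1, 0, 0.7, 0.6), "unknown model")
})

test_that("model family nests: CI -> WB without reverberation, WB -> NB at full trust", {
  grid <- condition_grid()
  for (seed in 1:5) {
    set.seed(seed)
    p_full <- ci_params(L_s_strong = runif(1, 0, 3), L_s_weak = runif(1, 0, 1),
                        L_impl = runif(1, 0, 2), L_expl = runif(1, 0, 2),
                        w_S = runif(1, 0.5, 1), w_P = runif(1, 0.5, 1))
    # WB with both weights at 1 equals NB
    p_unit <- p_full; p_unit$w_S <- 1; p_unit$w_P <- 1
    expect_equal(predict_log_posterior("WB", p_unit, grid),
                 predict_log_posterior("NB", p_unit, grid))
    # removing the reverberated messages from CI leaves the WB factors
    inp <- circinf:::condition_inputs(p_full, grid$group, grid$cue)
    wb_manual <- loop_factor(inp$L_S, p_full$w_S) +
      loop_factor(inp$L_Pr, inp$w_P)
    expect_equal(predict_log_posterior("WB", p_full, grid), wb_manual)
  }
})

test_that("finite-difference slopes agree with the analytic oracles", {
  for (w_S in c(0.55, 0.66, 0.77, 0.95)) {
    for (w_P in c(0.59, 0.8, 0.95)) {
      p <- ci_params(w_S = w_S, w_P = w_P)
      expect_equal(slope_at("NB", p), 1, tolerance = 1e-6)
      expect_equal(slope_at("WB", p), 2 * w_S - 1, tolerance = 1e-6)
      expect_equal(slope_at("CI", p),
                   (2 * w_S - 1) * (2 * w_S + 2 * w_P - 1),
                   tolerance = 1e-6)
    }
  }
  expect_error(slope_at("NB", ci_params(), step = 0), "positive")
})

test_that("CI slope at zero sensory input is non-increasing in the prior magnitude", {
  for (w_S in c(0.6, 0.77, 0.9)) {
    for (w_P in c(0.59, 0.75, 0.9)) {
      p <- ci_params(w_S = w_S, w_P = w_P)
      slopes <- vapply(seq(0, 3, by = 0.25),
                       function(pr) slope_at("CI", p, L_prior = pr),
                       numeric(1))
      expect_true(all(diff(slopes) <= 1e-8))
      # and symmetric in the sign of the prior
      expect_equal(slope_at("CI", p, L_prior = -1.5),
                   slope_at("CI", p, L_prior = 1.5), tolerance = 1e-8)
    }
  }
})

test_that("tilted group differs from a zero-prior normal cube only under CI", {
  p <- ci_params(L_s_strong = 1.2, L_s_weak = 0.5, L_impl = 0, L_expl = 0,
                 w_S = 0.7, w_P = 0.8)
  tilted <- list(group = "tilted", cue = "strong_supp")
  none <- list(group = "none", cue = "strong_supp")
  # WB: with all prior magnitudes 0 the prior branch is 0 either way
  expect_equal(predict_log_posterior("WB", p, tilted),
               predict_log_posterior("WB", p, none))
  # CI: the reverberated sensory message passes through the prior weight,
  # so pinning w_P at 0.5 (tilted) changes the prediction
  expect_false(isTRUE(all.equal(predict_log_posterior("CI", p, tilted),
                                predict_log_posterior("CI", p, none))))
  # but not when the sensory input is absent
  expect_equal(
    predict_log_posterior("CI", p, list(group = "tilted", cue = "ambiguous")),
    predict_log_posterior("CI", p, list(group = "none", cue = "ambiguous")))
})

test_that("group differences are cue-independent under NB but not under CI", {
  p <- default_ground_truth()
  cues <- data.frame(cue = cue_levels)
  diff_by_cue <- function(model) {
    predict_log_posterior(model, p, transform(cues, group = "supporting")) -
      predict_log_posterior(model, p, transform(cues, group = "contradicting"))
  }
  nb <- diff_by_cue("NB")
  expect_true(max(nb) - min(nb) < 1e-12)     # pure additivity
  ci <- diff_by_cue("CI")
  expect_gt(max(ci) - min(ci), 0.01)         # cue x instruction interaction
})

test_that("decision rules map log-odds to report probabilities", {
  expect_equal(response_probability(0), 0.5)
  for (x in c(-2, 0, 2)) {
    expect_equal(response_probability(x, "softmax", beta = 1),
                 response_probability(x, "matching"))
  }
  expect_gt(response_probability(0.1, "softmax", beta = 200), 0.999)
  expect_error(response_probability(0, "softmax", beta = 0), "positive")
})

test_that("parameter validation enforces magnitude and weight domains", {
  expect_error(ci_params(L_impl = -0.1), "non-negative")
  expect_error(ci_params(w_S = 0.4), "\\[0.5, 1\\]")
  expect_error(ci_params(w_P = 1.01), "\\[0.5, 1\\]")
  expect_error(ci_params(beta = -1), "positive")
  expect_error(ci_params(L_expl_SFA = 1), "both")
})
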