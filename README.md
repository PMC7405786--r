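# circinf

Circular-inference modelling of bistable Necker-cube perception.

The Necker cube is seen either "from above" (SFA) or "from below" (SFB),
with a spontaneous population bias toward SFA. When observers report their
interpretation repeatedly while shading cues and verbal instructions push
perception around, the fraction of SFA reports — the *relative
predominance* (RP) — traces how sensory evidence and priors combine.
`circinf` is for psychophysicists and computational modellers who want to
ask, on such two-alternative forced-choice data: is that combination
Bayes-optimal, merely down-weighted, or *circular* — amplified by
messages reverberating through the perceptual hierarchy?

The package implements three posterior models on the log-odds scale
(writing `F(L, w) = log[(w e^L + 1 − w) / ((1 − w) e^L + w)]` for the
weighted message with trust `w ∈ [0.5, 1]`):

| model | posterior log-odds `L_RP` |
|---|---|
| naive Bayes (NB) | `L_S + L_Pr` |
| weighted Bayes (WB) | `F(L_S, w_S) + F(L_Pr, w_P)` |
| circular inference (CI) | `F(L_S + I, w_S) + F(L_Pr + I, w_P)`, `I = F(L_S, w_S) + F(L_Pr, w_P)` |

where `L_S` is the signed sensory log-likelihood ratio, `L_Pr = L_impl +
L_expl` the total prior, and reports follow probability matching
(`P(SFA) = inv_logit(L_RP)`). Around zero the three models predict slopes
of exactly 1, `2w_S − 1 ≤ 1`, and `(2w_S − 1)(2w_S + 2w_P − 1)` (> 1 at
high trust); only CI predicts a cue-by-prior interaction. The package
simulates the full four-group experiment, summarises trials into RP and
log-odds fit points (Tukey-fence participant screening included), fits
the models by 100-restart constrained least squares, and compares them
with `BIC = n log(σ²) + k log(n)` plus leave-one-participant-out
jackknife resampling.

## Worked example

Simulate the default experiment (55 participants; ground truth CI with
`w_S = 0.66`, `w_P = 0.59`), screen, fit, and compare:

```r
library(circinf)
design  <- build_design(seed = 1)                     # 55 x 750 trials
trials  <- simulate_dataset(design, sim_config(model = "CI", seed = 1))
screened <- exclude_outliers(compute_rp(trials))
points  <- to_fit_points(screened$rp)                 # 5 points/participant
fits <- lapply(setNames(model_ids, model_ids), function(m)
  fit_model(points, m, n_restarts = 100, seed = 1))
compare_models(fits)
```

```
<ci_comparison>
BIC:
     NB      WB      CI 
-914.76 -952.30 -976.06 
best model: CI
delta BIC (row minus column sign convention: positive favours row):
      NB     WB     CI
NB  0.00 -37.54 -61.30
WB 37.54   0.00 -23.76
CI 61.30  23.76   0.00
```

The generating CI model wins decisively (ΔBIC 23.8 over WB, 61.3 over
NB; differences above 6 are conventionally strong evidence), and its fit
recovers the generating weights:

```r
fits$CI
#> <ci_fit> CI (symmetric): mse = 0.025429 over n = 275 points, k = 6
#> L_s_strong   L_s_weak     L_impl     L_expl        w_S        w_P 
#>    10.0000     0.9844     2.7280     2.7750     0.6463     0.5921 
```

`w_S = 0.646` and `w_P = 0.592` sit close to the truth (0.66 / 0.59);
the magnitude estimates are softer — the objective surface trades
magnitudes against weights (see the methods vignette), which is why
recovery is judged on weights averaged over replicated experiments.
`jackknife(points, full_fits = fits)` then refits every leave-one-out
subsample to check the comparison is not driven by single participants,
and `run_pipeline()` chains all of the above with every table persisted.
A thin CLI over the same functions lives at
`inst/scripts/circinf-pipeline.R` (subcommands `simulate`, `preprocess`,
`fit`, `compare`, `recover`, `run-all`).

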