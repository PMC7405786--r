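---
title: "Modelling bistable Necker-cube perception with circular inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bistable Necker-cube perception with circular inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circinf)
```

## The problem

The Necker cube is an ambiguous line drawing that observers spontaneously
see in one of two depth configurations, "seen from above" (SFA) or "seen
from below" (SFB), with a well-known population-level bias toward SFA.
In the experimental design this package emulates and analyses, observers
continuously view one cube per run and report their current interpretation
whenever a sound plays (25 sounds per run, 5 runs per block, 6 blocks).
Sensory evidence is manipulated within subject by shading cues of two
strengths that either support or contradict the SFA bias (blocks 1 and 4
are always ambiguous; the four cued conditions are randomly assigned to
the remaining blocks). Prior knowledge is manipulated between subjects in
four groups: a tilted cube that neutralises the viewpoint prior, and
upright cubes with supporting, contradicting, or no verbal instructions
(default group sizes 12, 14, 14, 15).

The quantity analysed is the *relative predominance* (RP): the fraction
of trials on which SFA was reported, per participant and condition, with
the two ambiguous blocks pooled — five RP values per participant. On the
log-odds scale, $L_{RP} = \log \frac{RP}{1-RP}$ is treated as the
posterior log-odds of the SFA interpretation, under the assumption that
reports follow probability matching.

## The three models

All three models combine a sensory log-likelihood ratio $L_S$ (signed by
cue orientation, with magnitudes $L_{s,strong}$, $L_{s,weak}$ free), an
implicit prior $L_{impl} \ge 0$, and an instruction-induced explicit
prior $L_{expl}$ (positive for supporting, negative for contradicting
instructions), with $L_{Pr} = L_{impl} + L_{expl}$:

* **Naive Bayes (NB)** — exact inference with full trust:
  $L_{RP} = L_S + L_{Pr}$.
* **Weighted Bayes (WB)** — exact inference with partial trust:
  $L_{RP} = F(L_S, w_S) + F(L_{Pr}, w_P)$, where
  $F(L, w) = \log \frac{w e^L + 1 - w}{(1-w) e^L + w}$
  is the weighted message a node passes onward. $F$ is odd in $L$,
  saturates at $\pm\log\frac{w}{1-w}$, vanishes at the uninformative
  weight $w = 0.5$, and is the identity at $w = 1$.
* **Circular inference (CI)** — weighted messages that additionally
  reverberate once through the loop, corrupting each branch with the
  other's message:
  $L_{RP} = F(L_S + I, w_S) + F(L_{Pr} + I, w_P)$ with
  $I = F(L_S, w_S) + F(L_{Pr}, w_P)$.

With unit weights and no priors the CI posterior is $3 L_S$ — the
sensory message is counted three times — and around $L_S = 0$ the slopes
of $L_{RP}$ in $L_S$ are exactly $1$ (NB), $2 w_S - 1 \le 1$ (WB), and
$(2 w_S - 1)(2 w_S + 2 w_P - 1)$ (CI), which exceeds 1 at high trust.
Only CI predicts both an amplified cue effect and a cue-by-prior
interaction (stronger priors flatten the curve); under NB the group
difference in $L_{RP}$ is the same at every cue. These closed forms are
used as oracles for the finite-difference `slope_at()` (central
difference, default step `1e-4`, chosen to balance truncation against
rounding in double precision).

For the tilted cube the viewpoint prior carries no information about the
drawing, so both prior magnitudes are dropped *and* $w_P$ is pinned at
0.5 for that group; under CI (but not WB) this still changes the
predictions whenever $L_S \neq 0$, because the reverberated sensory
message passes through the prior weight. The `shared_wP` variant lifts
this constraint as a control, `asymmetric_expl` splits $L_{expl}$ into
SFA/SFB magnitudes, and `softmax` adds a global decision gain
$\beta$ (probability matching is $\beta = 1$).

## Parameters, bounds, and fitting

All log-odds magnitudes are constrained non-negative, with the sign
applied by the design cell — this is the symmetry assumption that keeps
the parameterisation identifiable, and it makes the symmetric NB model a
4-parameter model and WB/CI 6-parameter models. Magnitudes are bounded
above at 10: at 125 trials per condition, posterior odds beyond $e^{10}$
are indistinguishable from certainty. Weights live in the closed interval
$[0.5, 1]$; both endpoints are analytically well defined. The ordering
$L_{s,strong} \ge L_{s,weak}$ is *not* enforced; recovery tests check
that it emerges from data.

Fitting minimises the mean squared distance between observed and
predicted $L_{RP}$ over every participant's five fit points (not group
means). Observed RP values of 0 or 1 are first clipped with the standard
empirical-logit correction $\varepsilon = 1/(2 n_{trials})$. The
objective is minimised with a bound-constrained quasi-Newton optimiser
(`optim(method = "L-BFGS-B")`, the standard R tool for smooth box-
constrained problems) restarted from 100 uniform random initialisations
inside the bounds. Restart initialisations are drawn sequentially from
the seed, so enlarging the restart budget extends rather than reshuffles
the explored set, and the best objective is non-increasing in the number
of restarts. Internally the objective collapses the fit points to
per-condition sufficient statistics, so an evaluation costs O(20 cells)
regardless of sample size.

Model comparison uses $BIC = n \log \sigma^2 + k \log n$ with the
natural logarithm (the standard BIC convention; the fitted error
variance $\sigma^2$ is the MSE). Stability is assessed by
leave-one-participant-out jackknife: one subsample per surviving
participant, each refit warm-started at the full-sample optimum plus 20
fresh restarts by default. The reduced restart budget is a deliberate
runtime knob — pass `n_restarts = 100` to `jackknife()` for the full
protocol — and the classical jackknife standard error
$\sqrt{\frac{N-1}{N}\sum_i (\theta_i - \bar\theta)^2}$ is reported
alongside the counts of subsamples whose $\Delta BIC$ exceeds 2, 4.5,
and 6.

## Outlier screening

Participants are screened on their grand-mean RP over all trials using
Tukey fences $Q_1 - 1.5\,IQR$ and $Q_3 + 1.5\,IQR$; values strictly
outside are excluded from all downstream steps. Quartiles use linear
interpolation with index $(n-1)q$ (`quantile(type = 7)`), a convention
that has to be fixed because the fences are sensitive to it at small
samples; degenerate samples (zero IQR) exclude no one, and fewer than
four participants is refused outright. Qualitative descriptions of
aberrant behaviour (negative cue slopes, flat at-or-below-chance curves,
RP pinned near 0/1 when ambiguous) have no quantified thresholds, so
`flag_qualitative()` reports them without removing anyone.

## What the synthetic generator emulates

`simulate_dataset()` draws each binary report independently from the
ground-truth model's posterior via probability matching — the same
independence assumption the models make. Two optional departures exist
purely as diagnostics: `persistence_rho` introduces within-run Markov
carry-over (visible as positive lag-1 autocorrelation, which
`autocorrelation()` estimates with the standard sample estimator within
runs), and `heterogeneity_sd` jitters each participant's log-odds
magnitudes (never the weights, so the weight constraints stay intact).
Each participant draws from an RNG substream derived from the master
seed, making datasets reproducible participant by participant.

The default ground truth is CI with $w_S = 0.66$, $w_P = 0.59$ — the
weights this task elicits from healthy adults — and log-odds magnitudes
calibrated so the simulated curves reproduce the observed effect sizes:
$L_{impl} = 2.5$ and $L_{expl} = 2.4$ put the no-instruction ambiguous
RP near 0.60 (a tilt effect of about 0.10) and the contradicting-
instruction effect near 0.10, while $L_{s,strong} = 2.74$,
$L_{s,weak} = 0.80$ give a strong-cue RP span of about 0.30. A larger
cue span (the observed value is closer to 0.4) is *not* expressible by
this ground truth: both branches of the CI posterior saturate at
$\log\frac{w}{1-w}$, which caps the RP range these weights allow. The
calibration therefore reproduces the prior effects exactly and the cue
span as closely as the generating model permits. Simulated participants
are exchangeable within group by default — real data have individual
differences, sequential dependencies and lapses — so passing recovery
tests demonstrate that the *pipeline* identifies its own generating
process at study scale, not that real data are this clean.

## Identifiability

Two structural facts surfaced by the noiseless recovery tests are worth
knowing. First, under WB the sensory branch enters the predictions only
through the two weighted messages $F(L_{s,strong}, w_S)$ and
$F(L_{s,weak}, w_S)$: three parameters produce two numbers, so $w_S$ is
only set-identified (a ridge running down to the weight whose saturation
bound equals the required message). Under CI the reverberation term
couples the branches and restores point identification of both weights.
Second, at study-scale noise the CI objective surface is flat along
directions trading weights against magnitudes; this is why fitting uses
100 restarts, why weight recovery is assessed as a mean over replicated
experiments, and why magnitude estimates should be interpreted more
cautiously than weight estimates.

## Problem sizes used by the test-suite studies

The packaged studies use the full default design (55 participants, 125
trials per cued condition, 250 ambiguous) for parameter recovery (10
replicated experiments, 100 restarts each), model recovery (3 replicated
experiments fitting all three models), and one full jackknife (55
subsamples, warm-started refits). Structural and analytic checks run on
reduced designs (1–4 participants per group) since they do not depend on
sample size.

## Limitations

The package fits aggregate points with parameters shared across
participants, as the original analysis did; it does not implement
hierarchical random-effects fitting, variable loop counts (both
reverberation counts are fixed at 1), continuous-time bistable attractor
dynamics, or stimulus rendering. The linear mixed-effects omnibus
analysis of the behavioural data is out of scope; only the RP curves,
the chance-level signed-rank check, and the autocorrelation diagnostic
are provided on the model-free side.
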