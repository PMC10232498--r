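---
title: "Simulating and analysing context-dependent value decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing context-dependent value decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In context-dependent choice, a cue determines which feature dimension of a
compound stimulus (its colour or its motion direction) is currently relevant
for reward. The reward-maximising agent should compute the expected value of
the cued dimension (EV, the larger of the two relevant feature values) and
ignore the other dimension entirely. The empirical question this package
addresses computationally is whether the ignored dimension's value --- the
background expected value EV_back, i.e. the larger of the two irrelevant
feature values --- is nevertheless represented in value-sensitive cortex, and
whether such a parallel representation competes with the relevant value
signal in a way that is gated by how strongly the current task context is
encoded.

Because the corresponding fMRI data cannot be regenerated at a desk, the
package is built around a *generative twin* of the full experiment: every
analysis stage is implemented exactly as it would be applied to real data,
and a synthetic-data generator with known ground truth feeds it. Green tests
therefore establish that the analysis code detects what it should detect,
stays silent when nothing was planted, and reproduces the combinatorial
facts of the design --- not that any particular empirical claim about the
brain is true.

## The task design

A session has 4 blocks of 108 trials: 36 one-dimensional trials (only the
cued dimension is present) and 72 two-dimensional trials (both dimensions
present). The two relevant values always differ by 20 points and come from
{10, 30, 50, 70}, so EV is 30, 50 or 70. On 2D trials the two irrelevant
features take every ordered pairing of distinct values (12 pairings per
relevant pair), making EV_back 30, 50 or 70. A trial is *congruent* when the
side holding the larger relevant value also holds the larger irrelevant
value.

`generate_design()` enforces the pseudo-randomization constraints: the cued
context is stable for 4--7 trials; at most 3 same-dimensionality trials in a
row within a context run and 5 across runs; target side at most 4 in a row;
congruency at most 3 in a row; and no target feature on consecutive trials
(so EV repeats at most once, across a context switch). From a pool of
constraint-satisfying candidate designs, those in which the target value
repeats on more than 10% of trials --- overall or among congruent,
incongruent or 1D trials --- are discarded and one survivor is selected by
the seed. Per (EV, context) cell each block holds exactly 6 one-dimensional
and 12 two-dimensional trials, and the side-assignment scheme (each
unordered irrelevant pair appears in both orders with a common target side)
makes EV, EV_back and Congruency *exactly* orthogonal over the 2D set.

One interpretive choice: "no more than 3 same-dimensionality repetitions
within each context" is read as within a context *run* (a switch resets the
count); the global bound of 5 covers repetition across switches.

Inter-event intervals are truncated exponentials with the stated means and
ranges (cue to stimulus: mean 0.6 s on [0.5, 2.5]; stimulus to outcome: mean
3.4 s on [1.5, 9]; outcome to next cue: mean 1.25 s on [0.7, 6]), sampled by
inverse CDF with the rate solved numerically so the truncated mean is exact.
`check_estimability()` convolves one boxcar regressor per stimulus (duration
1.6 s), two cue regressors split by context and three outcome regressors
split by EV with a canonical double-gamma HRF, samples at TR = 1.25 s, and
reports the variance inflation factor of every stimulus column; a VIF of 5
is the conventional conservative bound, and generated designs typically stay
below ~1.4.

## The staircase

Before value learning, an adaptive staircase equalises detection speed
across the eight perceptual features by moving each feature's intensity
parameter theta (motion coherence, colour speed) proportionally to the
relative deviation of its recent mean RT from an anchor:

theta' = theta + alpha * theta * (meanRT - anchorRT) / anchorRT.

Block 1 (72 trials) ends with one adjustment per feature at alpha = 1
against the mean RT of the last 48 correct trials. Block 2 computes a fresh
anchor from 24 motion-cued trials and then adjusts a feature after every
three correct answers to it, at most six times, with alpha falling from 0.6
to 0.1. The procedure does not prescribe an observer, so `make_observer()`
supplies one:
RT = a_i + b/theta + Gaussian noise, which is monotone in theta and has the
analytic equilibrium theta* = b / (anchor - a_i). Between-feature RT
variance reliably shrinks for heterogeneous offsets a_i; with identical
features the procedure induces no systematic drift.

## Behaviour

`simulate_behavior()` is the generative twin of the RT and accuracy models:
log RT is linear in EV, Congruency, Congruency x EV_back (and optionally
Congruency x EV) plus four nuisance terms (trial index, target side, switch
distance, context), with a Gaussian subject intercept; accuracy is Bernoulli
with a logit-linear predictor of the same shape whose fourth term is
Congruency x switch. Congruency is effects-coded (incongruent = +1), all
regressors are z-scaled exactly as the fitting functions scale them, and the
default intercepts put RTs near 0.9 s and accuracy near 0.9. Default effect
sizes are package parameters with no external referent; they are small on the log scale (e.g. 0.03 for Congruency)
but sized so that a dozen simulated subjects recover them.

`fit_rt_ladder()` fits the nested mixed-model sequence baseline+EV ->
+Congruency -> +EV_back -> +Congruency:EV_back by maximum likelihood
(`lme4::lmer`, subject random intercepts) with likelihood-ratio tests
between adjacent models, plus an AIC-compared alternative that replaces
EV_back with the overall (mean) irrelevant value. `fit_accuracy_ladder()`
mirrors it with a binomial family; its default engine uses fixed subject
intercepts (`glm`) because the calibration suites refit it hundreds of
times, with `engine = "glmer"` available. Complete separation is flagged
and a Haldane-corrected intercept summary returned. `congruency_contrasts()`
runs the paired t-tests (incongruent vs 1D, congruent vs 1D, incongruent vs
congruent) on per-subject mean log RTs with Benjamini-Hochberg adjustment.

## Synthetic voxel patterns

`make_codebook()` constructs unit-norm voxel codes: value codes whose
pairwise inner products are rho^(|dv|/20) (graded similarity), a background
value codebook overlapping the relevant one by omega, and two context codes
exactly orthogonal to everything else. `simulate_patterns()` mixes them per
trial:

pattern = g_ctx c(context) + g_EV u_rel(EV) + [2D] g_back u_back(EV_back) + noise

with g_ctx log-normal around a_ctx, g_back = a_back (1 + s_back (EV_back -
50)/20), and the *gated competition*

g_EV = max(0, a_EV - lambda exp(-m g_ctx) g_back):

the background gain suppresses the relevant gain (strength lambda), and a
strong context signal attenuates that suppression (strength m). Voxel noise
is heteroscedastic (log-normal per-voxel SDs) with AR(1) spatial
correlation; matched residual matrices are drawn from the same noise model
so noise normalization downstream is non-trivial. Per-trial ground-truth
gains are exported, so every planted quantity is recomputable without
re-simulation.

None of rho, omega, lambda, m or the noise level has an empirical referent
at desk scale; they are free parameters validated purely by recovery. The defaults
(rho = 0.5, omega = 0.7, lambda = 2.0, m = 1.2, a_back = 1.0, s_back = 0.8,
a_ctx = 1.5, noise SD 0.5) were chosen once so that *every* planted
mechanism is recoverable with a 12-subject, ~100-voxel cohort, and then
frozen. This puts value decoding near 0.6 balanced accuracy --- higher than
typical empirical ventromedial prefrontal decoding (~0.35) --- a deliberate
signal-to-noise choice for desk-scale recovery testing, not an empirical
target. The patterns are generated at response level; no HRF convolution or
trial-wise GLM deconvolution is simulated, and the volume-selection step of
real pipelines is an identity here.

## RSA

`prepare_condition_patterns()` averages accurate 2D trials into the 9
(EV, EV_back) condition means per run, normalizes voxels by their residual
SD (default) or by Ledoit-Wolf shrinkage whitening (after which Euclidean
distances are Mahalanobis distances), and subtracts the across-condition
mean pattern. `crossrun_rdm()` computes plain Euclidean distances only
*across* runs (mean over ordered run pairs), so the diagonal is meaningful
and noise does not bias same-condition cells toward zero dissimilarity.

Modelling the 45 unique cells requires care on two counts:

1. **Frequency bias.** The design frequencies of the 9 conditions are a
   function of the EV_back level (4, 8 or 12 trials per block), so the
   noisier means of rare conditions masquerade as EV_back similarity
   structure. Categorical frequency intercepts cannot fix this: fixed ones
   are *exactly* collinear with the EV_back similarity covariates, random
   ones under-absorb the bias (null type-I error approached 1). Instead
   each cell is divided by its exactly computable null noise scale --- the
   expected null distance is proportional to the square root of the summed
   variance factors of the two mean-subtracted condition means, a known
   function of the per-run trial counts --- after which the expected null
   dissimilarity is constant across cells.

2. **Cell dependence.** Cells within a subject share condition means, so a
   pooled likelihood over the 45 cells miscalibrates its tests (most were
   conservative). Moreover, over the unique upper-triangle cells
   |dEV_back| is *exactly* additive in condition main effects, so engines
   that absorb additive condition structure cannot test it at all. The
   default engine is therefore two-stage, the standard summary-statistics
   approach of the RSA literature: per-subject Gamma regressions with an
   inverse link on the noise-equalized distances, then one-sample t-tests
   of each coefficient across subjects. This calibrates (verified over
   hundreds of null replicates) because subjects are independent and the
   equalized null cell means are exactly constant. A pooled
   likelihood-ratio ladder remains available as `engine = "pooled_lr"`,
   with the caveat documented.

With the inverse link, "greater dissimilarity for different values" appears
as a negative coefficient.

## Decoding

`fit_multinomial()` is the package's own L2-penalized multinomial logistic
classifier (penalty 1/C on non-intercept weights, C = 1 by default,
reference-class coding), fitted by damped Newton iterations to a gradient
infinity-norm below 1e-6; the problem is strictly convex, so refits are
bit-reproducible. Voxels are z-scored within run before classification,
mirroring the per-block time-series standardization of real pipelines ---
without it, heteroscedastic voxels dominate the fit.

`loro_decode()` trains on behaviourally accurate 1D trials of three runs
(up-sampled so every EV x context x chosen-side cell has equal count,
preferring duplicates from under-represented blocks), predicts class
probabilities for every trial of the held-out run --- each trial predicted
exactly once, by the fold holding its own run --- and clips probabilities to
[0.00001, 0.99999]. `ovr_evback_decode()` trains three one-vs-rest logistic
classifiers on accurate 2D trials (balanced by EV x context x EV_back, with
sample weights equalizing the total weight of the one and the rest class),
renormalizes the three probabilities to sum to one, then clips; clipped
vectors are not renormalized again, so sums may deviate from 1 by a few
1e-5. Balanced accuracy averages correctness within (subject, fold, label)
before averaging across, and argmax ties count as incorrect.
`aggregate_combinations()` averages accurate-2D probabilities within the 36
EV x (irrelevant chosen, irrelevant unchosen) cells.

## Linking models

`make_link_records()` joins the three classifiers per trial and derives
P_EV, P_EVback and P_other (the value classifier's probabilities of the
objective value, the background value, and the third value, the latter
defined only when EV != EV_back), logit(P_context) of the true context,
P_EVback_2D (the background classifier's probability of the correct class),
multinomial-logit transforms (mlogit(P_c) is the mean log-odds of c against
the other classes), within-subject z-scaling, and the "other value on
screen" filter flag.

No beta-family GLM engine exists in the dependency stack, so the package
fits beta regressions (logit mean link, common precision) by maximum
likelihood with analytic gradients (`betareg_ml()`); every effect table
records its engine. For the primary hypothesis tests the engine is
two-stage --- the beta regression is fitted per subject and each
coefficient is t-tested across subjects, with per-subject AICs summed for
model comparisons --- for the same reason as in the RSA module: the pooled
likelihood ignores within-subject dependence. It is not a small effect; the
value-similarity model stacks the three sum-to-one class probabilities of
each trial as separate rows, and its pooled likelihood-ratio tests showed
10-11% type-I error under the null, against 5% for the two-stage tests.

The fitted models are: the value-similarity model (P(class) on
|EV - class| and its interaction with EV_back, with a perceptual
feature-overlap control that coincides with the value distance on 1D
trials); the P_EV model (EV_back and logit(P_context), with AIC-compared
controls: minimum irrelevant value, congruency terms, perceptual presence
of the EV_back feature, EV = EV_back match); the EV/EV_back/Other
correlation asymmetry (Spearman correlations of the mlogit-transformed
probabilities on accurate 2D trials with EV != EV_back and the other value
on screen, Fisher-z, paired t-test, plus an AIC-compared regression twin);
the full P_EV model with the background classifier and its context
interaction, using EV_back-level intercepts per subject (which absorb the
EV_back main effect; a pooled `gaussian` engine on logit(P_EV) exhibits the
exact intercept-absorption invariance); and the behaviour links (the P_EVback
model including wrong trials with EV x EV_back and Congruency x Accuracy
terms, and the two-step term-selection logistic models of accuracy per
congruency subset, which remain likelihood-ratio tests on binomial GLMs).

`subject_effects()` extracts per-subject behavioural slopes from random
slopes (BLUP + fixed effect) and per-subject neural slopes by two-stage
least squares on logit(P_EV); `subject_correlations()` reports Pearson r
with Spearman rank p-values, the convention of between-subject brain-
behaviour scatter plots.

## Calibration and recovery testing

The acceptance suite verifies, beyond the combinatorial facts:

* **Null calibration.** Under the all-null generative world every
  inferential test's type-I error must lie in [0.03, 0.08] at alpha = 0.05.
  The suites run 600-800 null replicates per module (more than the minimal
  200, so that the band is meaningful against binomial noise: with ~16
  simultaneous checks at 200 replicates a perfectly calibrated suite would
  fail by chance more often than not). The RT/accuracy ladders use the
  behavioural generator with all slopes zero; the RDM tests use pure-noise
  patterns end to end; the linking models use a record-level null
  (classifier probabilities drawn from subject-heterogeneous flat
  Dirichlets, independent of every covariate) because decoding hundreds of
  cohorts is not affordable and the zero-signal pipeline induces exactly
  that independence.

* **Recovery.** With the default planted world, 50 replicates of the
  simulate-decode-link path (12 subjects, 96 voxels) must reproduce the
  qualitative sign pattern --- negative EV_back effect on P_EV;
  corr(P_EV, P_EVback) more negative than corr(P_EV, P_other); positive
  logit(P_context) x P_EVback_2D interaction; positive behavioural
  Congruency x EV_back interaction --- in at least 80% of replicates.

What a green suite does *not* establish: realistic BOLD autocorrelation,
physiological noise, or motion artifacts (the noise model is spatially
AR(1) Gaussian); HRF-level confounds in the pattern path (patterns are
response-level); or any claim about real brains. The generator emulates the
trial structure, near-ceiling behaviour, graded value codes and gated
competition --- the ingredients the analysis stack is supposed to detect.

## Numerical choices

Probabilities are clipped to [0.00001, 0.99999] before any logit-scale
computation. The multinomial classifier converges to gradient norm 1e-6 and
classifier ties count as errors. Beta regression starts from an OLS fit on
the logit scale and maximizes by BFGS with analytic gradients. Gamma
regressions use the inverse link throughout. Truncated-exponential rates are
solved by `uniroot` to 1e-12. All pipeline stages derive their seeds
deterministically from one master seed, and the full default pipeline is
byte-reproducible.
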