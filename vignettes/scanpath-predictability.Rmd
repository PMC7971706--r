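---
title: "Quantifying scan-path predictability: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying scan-path predictability: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeinfo)
```

## The model

A scan path is treated as a realization of a discrete-time categorical
process $X_1, X_2, \dots$ over the AOI alphabet $\{1,\dots,A\}$. Two
complementary summaries of its predictability are computed, both in
bits (log base 2 throughout; the choice of base only rescales every
measure):

* **Gaze transition entropy**,
  $\mathrm{GTE} = H(X_t \mid X_{t-1}) = H(X_t, X_{t-1}) - H(X_{t-1})$,
  the *remaining* uncertainty in the next fixation under a first-order
  Markov assumption.
* **Active information storage**,
  $\mathrm{AIS} = I(X_t^-; X_t) = H(X_t) + H(X_t^-) - H(X_t, X_t^-)$,
  the uncertainty *resolved* by an individually optimized past state
  $X_t^- = \{X_{t-l}\}_{l \in L}$.

When $L = \{1\}$ the two are exactly complementary,
$\mathrm{GTE} + \mathrm{AIS} = H(X_t)$. Local (per-fixation) variants
drop the expectation: $\mathrm{LAIS}(x_t) = \log_2 p(x_t\mid
x_t^-)/p(x_t)$ (possibly negative — a misinformative past) and
$\mathrm{LGTE}(x_t) = -\log_2 p(x_t \mid x_{t-1})$. These satisfy the
local chain rule $h(x_t|x_{t-1}) = h(x_t,x_{t-1}) - h(x_{t-1})$ and
average exactly to their global counterparts.

### Assumptions

* The process is treated as stationary over the recording for the
  purpose of estimating $p(\cdot)$: local values are evaluated per
  fixation, but the distributions behind them are plug-in estimates
  from **all** eligible samples of the full, consecutive scan path.
  Period effects are therefore changes in *which* realizations occur,
  evaluated under a common law.
* A finite predictive horizon exists: the past state is sought within
  lags $1..l_{\max}$ (default 5).

### Estimation conventions

* **Plug-in estimators, no analytic bias correction.** Relative
  frequencies over all eligible samples; finite-sample bias is handled
  through permutation testing only, so the reported raw values are the
  plain plug-in quantities.
* **Eligible samples.** For a lag set $L$, all measures use
  $t = \max(L)+1, \dots, n$. Measures with different lag sets each use
  their own eligible set; `min_history` can force a common base when an
  exact comparison is needed (the complementarity identity, for
  instance, holds to $10^{-10}$ only on the identical sample set).
* **LGTE is always the lag-1 conditional**, whatever the optimized lag
  set. This is the deliberate design of the comparison: the lag-1
  measure represents what a first-order analysis would see.
* Probabilities are stored for observed support only. An observed
  in-sample tuple never has probability zero, so local values are
  always finite.

## Optimizing the past state

Greedy forward selection (non-uniform embedding): starting from an
empty selection, each remaining candidate lag's conditional mutual
information with $X_t$, given the already selected lags, is computed on
the common eligible set $t > \max(\text{candidates}, \text{selected})$.
The best candidate is tested with a **max-statistic permutation test**:
in each surrogate round every candidate's column is permuted
independently (target and conditioning intact — exactly the tested
dependence is destroyed) and the maximum CMI across candidates is
recorded. The winner joins the selection if
$p \le \alpha$; otherwise the procedure stops ("no variable provides
new information"). Taking the maximum over candidates controls the
family-wise error of each selection step; because the surrogate CMIs
carry the same plug-in bias as the observed one, the bias cancels in
the comparison.

Numerical/testing choices:

* Default $\alpha = 0.05$ and 200 permutations — the smallest p-value,
  $1/201$, comfortably resolves $\alpha$, and `permutation_config()`
  enforces $n_\text{perm} \ge 1/\alpha - 1$.
* p-values use the add-one correction
  $p = (1 + \#\{\text{surrogate} \ge \text{observed}\})/(1 + n_\text{perm})$,
  so $p = 0$ is impossible.
* Ties in CMI break toward the smallest lag (parsimony toward the
  recent past).
* Forward selection only; no backward pruning pass. On memoryless
  sequences the probability of selecting *any* lag is calibrated at
  $\alpha$ (verified by simulation), and for already-selected
  conditioning the unconditional permutation scheme is, if anything,
  conservative, because it also destroys the candidate–conditioning
  dependence.
* One master seed; each greedy step derives its surrogate seed
  deterministically from it, so identical inputs and seed give
  identical embeddings, and the global RNG state is left untouched.
* A guard requires $n > 10A$ before optimization is attempted.

## The synthetic generator and its ground truth

`build_chain()` constructs order-$m$ chains whose conditional law for a
lagged tuple $u$ is
$(1-\rho)\,b + (\rho/k)\sum_{l \in L^\ast} \delta_{\sigma_l(u_l)}$,
with $b$ a base marginal, $L^\ast$ the active lags and $\sigma_l$ a
deterministic per-lag map. The mixture over *per-lag* maps (rather
than one joint map of the whole tuple) makes each active lag
individually informative, which is what renders multi-lag sets
recoverable by greedy forward selection; a joint map such as a modular
sum would hide all structure from single-lag statistics. Two map
families are provided:

* `"shift"` — cyclic shift by $l$; with $\rho = 1$ and lag 1 this is
  the deterministic cycle through all AOIs (a convenient exact test
  case: AIS $= \log_2 A$, GTE $= 0$).
* `"repeat"` — the gaze returns to the AOI fixated $l$ steps ago
  (refixation/perseveration dynamics). Its key property is that the
  base marginal is exactly stationary, so skewed AOI usage survives
  any coupling strength. Singleton even/odd lag sets also make
  $X_t$ and $X_{t-1}$ exactly independent (parity decoupling) — a
  clean embodiment of "structure invisible to a first-order measure".

`exact_measures()` is the analytic oracle: the chain is lifted to a
first-order chain on $m$-tuples, its stationary distribution solved on
the unique recurrent class (power iteration with a direct sparse-solve
fallback for periodic chains; several recurrent classes raise an
error), and the exact entropies of any lag set are obtained by
enumeration. Every estimator in the package is validated against it.

### Cohort defaults

`cohort_config()` encodes the study conditions the package emulates:
11 participants, one recording each of $\sim 866$ fixations (SD 74)
over 8 AOIs; 12 overtaking trials (6 easy, 6 hard, random order), each
with a 5-fixation baseline, a before-lane-change and an
after-lane-change period; inter-trial stretches unlabeled. Baseline
AOI use is heavily skewed (80% of mass on the dashboard and ego-lane
AOIs); task periods are more dispersed (0.64 on those two), so joint
entropy rises during the task while the distributional *shape* stays
close enough that joint-entropy normalization cancels the marginal
switch in measures that carry no genuine predictability signal.

Participants split into six first-order ({1}), four higher-order
({2}, {3}, {4}, {2}) and one memoryless chain. The higher-order sets
are singletons excluding lag 1, for two reasons stated as design goals:
their predictability — and any change in it — is structurally invisible
to the lag-1 measure (parity decoupling), and the injected effect is
homogeneous across the group, so the group-level mixed model tests a
common effect rather than a heterogeneous one (with four participants,
real effect heterogeneity is absorbed by the random slope and collapses
the Satterthwaite df). Predictability increases after the lane change
via a coupling boost $\rho: 0.8 \to 0.95$; this magnitude is calibrated
so that the injection is reliably detectable at the study's sample
sizes. Fixation durations are synthesized lognormal around per-period
means (630/530/500 ms), clamped inside the quality window so that
preprocessing leaves the synthetic recordings unchanged; they are
descriptive output only, never analyzed quantitatively.

What the generator does *not* emulate: saliency or image-computable
structure, smooth oculomotor dynamics, drift or nonstationarity within
periods, tracker noise and dropouts (confidence is 1.0), and any
coupling between fixation duration and AOI content. Passing tests on
this generator therefore validate the estimation and inference
machinery under known ground truth — not the behavioral realism of any
particular dataset.

## Preprocessing and period labelling

Fixations shorter than 100 ms or longer than 1500 ms, and samples with
tracker confidence below 0.9, are excluded; both duration bounds and
the confidence bound are inclusive on the retained side, since the
exclusion criteria are phrased as "below"/"above". Baselines are the
five quality-passing fixations immediately preceding a valid trial's
onset (fewer, with a warning, at sequence starts — data are kept rather
than trials dropped). The lane-change boundary is half-open,
$[\text{onset}, \text{lc})$ / $[\text{lc}, \text{end}]$, making the
period assignment a partition. Invalid trials label nothing. The AOI
alphabet is fixed by configuration (default 8) so unseen symbols are
errors, not silent alphabet growth; sessions are independent sequences
and symbols never span session boundaries.

## Period averages, normalization, and the mixed model

Local series are averaged within every (participant, trial, period)
cell and normalized by the matching mean local joint entropy — LAIS by
the joint entropy of $(x_t, x_t^-)$ with the *full* optimized past
state (consistent with the bound $\mathrm{AIS} \le H(X_t, X_t^-)$),
LGTE by that of $(x_t, x_{t-1})$. Normalization controls for changes in
the overall information content of the scan path, so that changes in
the normalized measures reflect predictability rather than dispersion.
Cells with fewer than two fixations or a zero joint entropy are flagged
invalid. Participants with an empty embedding are excluded from
AIS-side analysis and keep LGTE-only summaries.

The inference stage is a linear mixed model per group and measure, one
observation per (participant, trial, period) — trial-level observations
are the default because they match the residual degrees of freedom such
designs produce; pooling trials within period is available by averaging
the summaries first. Fixed effects: deviation-coded difficulty (easy
$+1$, hard $-1$: easy vs the grand mean), two Helmert contrasts for
period — baseline vs before lane change ($-1/2, +1/2, 0$) and their
mean vs after lane change ($-1/3, -1/3, +2/3$) — and their
interactions. The fractional scaling keeps the contrasts orthogonal and
zero-sum; it affects coefficients, not $t$ or $p$, and is recorded in
the design's metadata. Baseline observations carry the upcoming trial's
difficulty so the factorial is complete. Random structure: intercept
plus period-contrast slopes per participant, REML, Satterthwaite df via
`lmerTest`. With few participants the slope covariance is routinely
estimated at the boundary (singular); such fits are *kept* — a boundary
REML fit is a valid solution and its Satterthwaite df reflect the
estimated structure — and flagged in `glance()`; only a model that
cannot be fitted at all falls back to a random intercept, with a
warning. No multiplicity correction is applied across the two measures
and two groups; p-values are reported per model.

## Numerical choices and degenerate inputs

* Tuple distributions are coded in mixed radix and tabulated; entropy
  of a code vector is $-\sum \hat p \log_2 \hat p$ with $0\log 0 = 0$.
* Constant scan paths give zero CMI and $p = 1$ in the selection test.
* An empty lag set yields AIS 0 with a warning, and LAIS-side local
  columns `NA`.
* Plug-in distributions sum to 1 within $10^{-12}$; identities
  (decomposition, complementarity, averaging, local chain rule) hold to
  $10^{-10}$ on identical eligible samples, and are tested at that
  tolerance.
* Stationary distributions: power iteration to an $L_1$ tolerance of
  $10^{-14}$ (fast for the aperiodic mixtures built here), direct
  sparse solve as fallback; the recurrent class is found via strongly
  connected components of the support graph.

## Problem sizes used in the test suite

The suite validates identities on 100 random sequences of length 500;
oracle agreement on $10^5$-step simulations (within 0.02 bits);
embedding recovery on 20 seeded runs per true lag set at $n = 5000$,
$l_{\max} = 5$, 200 permutations; false-positive calibration on 200
memoryless sequences; the end-to-end cohort analogue on 50 seeded
replicates; and mixed-model exactness (OLS closed form at zero random
variance, to $10^{-8}$) plus 95%-CI coverage of an injected period
effect over 50 replicates. These sizes were chosen to make sampling
error small relative to the margins being tested while keeping the
whole suite runnable on a laptop in minutes.

## Known limitations

* Plug-in AIS is biased upward for large past states relative to the
  sample size; the permutation scheme controls *selection*, but
  reported raw AIS values for large selected sets at short $n$ still
  carry bias. Comparisons across participants with different lag-set
  sizes should use the normalized quantities.
* The greedy search can in principle miss purely synergistic multi-lag
  structure (dependencies invisible to every single lag given the
  current selection) — a known property of forward selection.
* Local measures evaluated under a single global law assume the law is
  shared across periods; strong within-recording nonstationarity would
  blur the interpretation of period contrasts.
* With very few participants per group the mixed model's slope
  covariance is weakly identified; Satterthwaite df can be small and
  power limited. This mirrors the reality of small-cohort designs
  rather than a numerical defect.
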