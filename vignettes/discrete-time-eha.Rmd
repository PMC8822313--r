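---
title: "Discrete-time event history analysis of response times: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete-time event history analysis of response times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dteha)
```

## The model

A response time is the waiting time until a qualitative event — a button
press — measured from a defined time zero (usually target onset). With a
fixed response deadline, some trials end without a response; all we know
for those is that the latency exceeds the deadline. They are
right-censored, of the "singly Type I" kind: one censoring time, set by
the experimenter, shared by all trials. Analyses that drop these trials
(or trim "too slow" responses) condition on responding early and bias
everything they estimate. Event history analysis keeps them.

We work in discrete time: the window (0, deadline] is partitioned into K
contiguous half-open bins (a, b]. With T the rank of the bin containing
the response,

* hazard: h(t) = P(T = t | T ≥ t)
* survivor: S(t) = P(T > t) = ∏_{i ≤ t} (1 − h(i)), F(t) = 1 − S(t)
* probability mass: P(t) = P(T = t) = h(t) · S(t − 1)
* conditional accuracy: ca(t) = P(correct | T = t)

The hazard is the primitive: it describes what happens *locally* at each
waiting time among trials still waiting, which is why two conditions can
differ sharply in h(t) while their S(t) or quantile summaries look almost
identical. A complete ordering of two hazard functions (h_A(t) > h_B(t)
for all t) implies a complete ordering of the distribution and survivor
functions — but not conversely; and hazard curves can cross while the
survivor curves do not, because S accumulates history. Both facts are
property-tested in the suite (`test-acceptance.R`, dominance block), the
second on a constructed early-peak/late-peak profile pair in
`crossing_hazard_pair()`.

The life-table estimators are the nonparametric ML estimates from the
per-bin counts: h(t) = E(t)/RS(t) with E the events and RS the risk set,
ca(t) = n_correct(t)/E(t), and the product-limit S. With no interior
censoring, P(t) reduces to E(t)/RS(1) exactly, and the estimators agree
with brute-force enumeration over the trial list (tested for small n).

### Standard errors

h, P and ca are per-bin proportions; their standard errors use
√(p(1 − p)/N) with N = RS(t), RS(1) and E(t) respectively. For S we use
Greenwood's product-limit formula

S(t) · √( Σ_{i ≤ t} E(i) / (RS(i) (RS(i) − E(i))) ).

This is a deliberate, documented choice: published worked examples of
this life table cite an unprinted recurrence for se(S) whose values match
no standard formula we could reconstruct (neither Greenwood nor any
binomial variant reproduces all of its printed digits), so the package
states its formula explicitly and the golden-value tests compare every
column *except* se_S. The recurrence could not be recovered; guessing it
would be worse than documenting the divergence.

### Conventions and degenerate inputs

* Bins are right-closed: rt = 400 ms with 40-ms bins falls in (360, 400].
* rt above the deadline and missing responses are both ingested as
  censored-at-K (`read_trials()` converts late responses with a logged
  count); interior censoring is possible only through an explicit
  `censor_bin` column (equipment failures and the like).
* h(t) is NA (not 0) once RS(t) = 0, and S propagates the NA: a curve
  that has exhausted its risk set has no estimate, rather than a fake one.
* ca(t) is NA exactly when E(t) = 0.
* All estimates are stored at full precision; `format_life_table()`
  rounds (3 decimals, ca to 2) only for display and export.
* Strata are participant × condition cells by default
  (`life_table_by()`); pooling is an explicit choice, because hazard
  shapes differ across individuals and pooled curves can resemble no
  participant.

## Hazard regression

Expanding each trial into one row per bin at risk (event indicator 1 only
in the event bin) turns discrete-time hazard modelling into a Bernoulli
GLM. The linear predictor is a polynomial in centered time (TIME − c,
c = 1 by default so the intercept is the bin-1 baseline) plus covariate
shifts and optional covariate × time interactions:

cloglog[h(t)] = ln(−ln(1 − h(t))) = α₀ + α₁(t−1) + α₂(t−1)² + α₃(t−1)³
+ β₁X₁ + β₂X₂ + β₃X₂(t−1).

The cloglog link is the default because events occur in continuous time
within a bin; its exponentiated coefficients are hazard ratios, invariant
to the bin width in the fine-bin limit. The logit link is available;
intercept-only fits give the same fitted probability under either link
(the pooled event rate), which the suite asserts.

Two exact identities anchor the implementation:

* an intercept-only fit returns cloglog (or logit) of
  total events / total person-trial-bin rows;
* a saturated fit (one dummy per bin) reproduces the life-table
  h(t) = E(t)/RS(t) per bin — the GLM and the life table are the same
  ML problem under that parameterisation. The suite checks agreement to
  1e−6 on simulated data for both links.

Estimation is single-level ML (`stats::glm`). Repeated-measures
clustering (several participants in one fit) is out of scope; the fit
warns when it detects pooled participants. Non-convergence, separation
(fitted hazards at the (0,1) boundary) and rank deficiency raise errors
instead of returning silent estimates. Wald intervals on the link scale,
exponentiated, accompany the hazard ratios — the standard presentation
for this model family.

Parameter recovery is validated generatively: `sample_hazard_model()`
draws trials whose true hazards follow the model equation, and the
acceptance suite refits 20 replicates of n = 5,000 trials from a cubic
baseline (α = −3.5, 0.55, −0.02, 0.0008 — a hazard rising from ≈0.03 to
near 1 across 15 × 40 ms bins, the shape typical of a speeded task) with
a binary covariate (β = 0.5), a continuous covariate (β = 0.3) and its
time interaction (γ = −0.06), requiring every coefficient within 3
reported SEs in at least 18 of 20 replicates. The truth values were fixed
once, as a realistic configuration, before any testing; n = 5,000 trials
keeps a replicate's fit under a second without starving the cubic term.

## ca(t)-state transition coding

For two conditions A (congruent) and B (incongruent), each participant ×
bin cell is coded by comparing conditional accuracies: exact extremes
`P` (ca_A = 1, ca_B = 0) and `N` (the reverse); threshold differences
`p`/`n` (|ca_A − ca_B| ≥ 0.2); `all` (both strictly > 0.8);
single-condition codes `cc`, `ic`, `ci`, `ii` when only one condition
emitted responses; `x` when neither did; `?` otherwise. Codes map to
evidence classes (positive effect, negative effect, none, other) for
plotting elsewhere; the package exports matrices and long tables only.

Three choices the rule list itself leaves open:

* precedence is exact-extreme → threshold → all → `?`: a (1, 0) bin
  satisfies both `P` and `p`, and the most specific label wins;
* "> .8 for both" is strict, as printed;
* single-condition codes classify by the sign of the implied effect
  (`cc`, `ii` positive; `ic`, `ci` negative); the mapping is exposed as
  an argument (`default_code_classes()`) since reasonable alternatives
  exist.

Threshold comparisons absorb float noise at 1e−9: accuracies are ratios
of small counts, and 0.7 − 0.5 in binary arithmetic falls a hair short
of 0.2.

## Jackknife inference for latency parameters

Landmarks of a hazard or accuracy curve (the bottom of a dip, an onset
threshold crossing) are hard to read off single-participant curves.
The leave-one-out jackknife replaces participant i's curve by the mean
of the other N − 1 curves; each subsample curve is smooth, the landmark
is extracted per subsample within a pre-registered region of interest,
and the N values enter a standard ANOVA. Because every participant
appears in N − 1 subsamples, subsample variance is the individual
variance divided by (N − 1)² — exactly, for any statistic linear in the
curves — so the F statistic must be divided by (N − 1)², with p
recomputed at unchanged degrees of freedom. The suite verifies the
equality F_corrected = F_individual to 1e−9 on random data via a dual
computation (jackknife pipeline vs direct repeated-measures ANOVA on the
individual values), and that N = 2 makes the correction the identity.

Choices: the default ANOVA is one-way repeated measures (conditions
crossed with subsamples), matching the within-participant designs this
procedure is used for; a between-groups option exists; only the one-way
correction is claimed — factorial designs are not developed here. Ties
in extrema break to the earliest bin (temporal priority). A zero effect
sum of squares reports F = 0, p = 1 rather than a ratio of float
residuals.

## The synthetic generator

The generator serves two roles: validation fixtures with known truth,
and design exploration.

* `discrete_profile()` + `sample_discrete()`: trials from arbitrary
  per-bin h(t) and ca(t); the implied S, P and censored fraction are
  closed-form. Sampling draws the event bin from the implied mass
  function (distributionally identical to the bin-by-bin Bernoulli walk)
  and places the rt uniformly inside the bin.
* `parametric_family()` + `sample_continuous()`: i.i.d. draws from the
  exponential, Weibull, gamma or log-normal family, censored at a fixed
  deadline — flat, increasing, saturating and peaked hazard shapes
  respectively. `discretize_true_hazard()` maps a family and a binning
  scheme to the exact discrete h(t) = [S(a) − S(b)]/S(a), the
  interval-censored truth that binned estimates converge to; for the
  exponential it is constant, 1 − e^(−rΔ).
* `sample_hazard_model()`: trials from the regression model itself.

What the generator emulates: right-censored trial tables with
bin-resolved hazards and accuracies under a fixed deadline. What it does
not: sequential dependencies across trials, participant heterogeneity
within a profile, time-varying covariates, and fast-guess mixtures.
Passing recovery tests therefore demonstrates estimator correctness
under the stated sampling model, not robustness to those features of
real data.

Recovery tolerances are statistical, not tuned: per-bin estimates must
fall within 3 binomial SEs of truth where the normal approximation is
defensible (expected bin count ≥ 5); far-tail bins with expected counts
below that are bounded by their Poisson 99.9% quantile instead, since a
z-score on 0.7 expected events is meaningless. Simulation sizes
(10,000–20,000 trials for consistency checks, 5,000 × 20 replicates for
regression recovery, 1,000 pairs for the dominance property) were chosen
to make the checks sharp while keeping the full suite in the
tens-of-seconds range on a single core.

## Known limitations

* No continuous-time estimation (Kaplan–Meier, Cox, piecewise
  exponential): discrete time is the method's deliberate trade of
  temporal resolution for stability at realistic trial counts.
* No mixed-effects/GEE/Bayesian hazard models: inference is per
  participant (small-N logic) or single-level with a warning.
* h(t) and ca(t) are modelled separately; no joint likelihood is
  claimed.
* No plotting: every object exports to plain data frames/CSV for the
  user's plotting stack.
* se_S follows Greenwood; published tables using an unprinted recurrence
  will differ in that one column (see above).
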