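---
title: "Adaptive olfactory threshold estimation: models, procedures and agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive olfactory threshold estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfquest)
```

## The measurement problem

An olfactory detection threshold locates the weakest odorant concentration
a person can reliably tell apart from odorless blanks. The Sniffin' Sticks
threshold set discretizes the concentration axis into 16 pens forming a
geometric dilution series (4% v/v at pen 1, ratio 2, so pen $k$ carries
$4 \cdot 2^{-(k-1)}$ percent v/v; `pen_concentration()`). Each trial is a
3-alternative forced choice with chance level $1/3$. Thresholds are
reported on the pen axis: higher pen number = weaker detectable stimulus =
more sensitive nose.

Two facts shape everything in this package. First, the stimulus set is
*discrete and bounded*: procedures must round, clamp at pens 1 and 16, and
deal with participants whose sensitivity falls outside the measurable
range. Second, responses are *forced-choice*: a participant who smells
nothing still answers correctly with probability $1/3$, so every trial
sequence is contaminated by lucky guesses.

## The psychometric model

Responses are modelled by a Weibull psychometric function for
3-AFC tasks,
$$\Psi(x) = \lambda\gamma + (1-\lambda)\left[1 - (1-\gamma)
  e^{-10^{\beta (x + T)}}\right],$$
with guess rate $\gamma = 1/3$, lapse rate $\lambda$ (default 0.01,
capping performance at $\lambda\gamma + 1 - \lambda \approx 0.99$), slope
$\beta$, and threshold $T$. The stimulus axis is oriented so that lower
pen numbers (stronger stimuli) yield higher success probabilities; with
the default parameters the attainable range is 0.33–0.99
(`p_correct()`, `level_at_p()`).

**Slope units.** We express $\beta$ per log$_{10}$-concentration unit by
default, the standard convention for this Weibull parametrization in
adaptive psychophysics. Pens are spaced $\log_{10} 2 \approx 0.301$ of
those units apart, so $\beta = 3.5$ corresponds to an effective
$3.5\log_{10}2 \approx 1.05$ per pen — a transition spanning roughly two to
three pens. The alternative reading, 3.5 *per pen*, would compress the
entire transition inside a single pen step; under that reading the
procedure's 20-trial operating point (below) cannot reach its nominal 80%
target at all, because the threshold estimate's unavoidable spread of
about half a pen traverses nearly the whole probability range. Simulation
bears this out: with slope per log$_{10}$ unit the measured operating
point is 80.0%, with slope per pen it is 73%. We therefore adopt the
log$_{10}$ convention (`slope_unit = "log10"`); `slope_unit = "pen"`
remains available for explicitly pen-scaled analyses.

**Threshold anchoring.** `weibull_pf()` stores $T$ as the level at which
$\Psi$ equals a configured target probability (0.80 by default), making
"the procedure targets the threshold at 80% correct" literal. Internally
this is the $x + T = 0$ point of the formula shifted by a closed-form
offset ($+0.0255$ pens at the default parameters).

## The staircase

`staircase_run()` follows the standard protocol. Phase A starts at pen 16
or 15 (balanced across participants in cohorts) and moves two pens
stronger after each miss; a pen identified twice consecutively becomes the
starting concentration. Phase B is a one-up/two-down staircase with step
1: one pen stronger after each miss, one pen weaker after two consecutive
hits *at the same pen* (the hit counter resets after every move). A
reversal is logged, at the pen where the direction-changing response
occurred and before moving, whenever the intended direction differs from
the previous intended one; the starting concentration is not counted as a
reversal. Seven reversals end the run; the raw threshold is the mean of
the last four reversal pens.

Boundary rules: a demanded move below pen 1 re-presents pen 1; a demanded
move above pen 16 terminates the run with the sentinel threshold 16. A
configurable trial cap (default 200) guards against the non-terminating
loop a pure guesser could produce at pen 1 — human runs end because pen 1
is eventually identified, but simulations need the guard.

Two conventions were genuinely open and are fixed as follows: reversal
values are recorded *pre-move* (the common reading of "reversal
concentration"), and phase-A trials do not seed the phase-B hit counter
(phase B starts fresh at the starting pen).

## The Bayesian adaptive procedure

`quest_run()` maintains a posterior over candidate thresholds on a grid
with 0.01-pen granularity. The prior is normal with SD 20 pen units
centred on pen 7 — effectively flat over the pen range; the grid spans the
start pen ±1.5 prior SDs ([−23, 37] by default), wide enough to represent
estimates below pen 1, which occur in practice and matter for cleaning.
The grid range is a package choice (nothing narrower is defensible once
sub-pen-1 estimates must be representable); estimates are insensitive to
widening it further because the likelihood plateaus far from the data
carry negligible mass.

Each trial: (1) the raw proposal is the current posterior mean (the
placement rule is configurable — mean, mode or quantile — because the
estimator used by the original instrumentation is not recoverable;
posterior-mean placement is standard practice and matches the final
estimate, and an expected-information-gain placement we evaluated gave a
*wider* estimate distribution on this discrete grid); (2) the proposal is
rounded to the nearest pen, ties toward the stronger pen; (3) clamped into
[1, 16]; (4) if the last two trials presented the same pen and both were
correct, the next pen is forced one step weaker — both incorrect, one step
stronger — and re-clamped. The posterior is updated with the likelihood of
the response at the *actually presented* pen, so clamping and overrides
are correctly accounted for. After a fixed 20 trials the estimate is the
posterior mean. Triplet positions are drawn uniformly at random (the
staircase instead cycles first/middle/last; `target_position()`).

Numerics: the posterior is kept in log space and renormalized after every
update (`sum(exp(log_posterior)) == 1` to 1e-12); per-pen likelihood rows
are precomputed at initialization; with $\lambda > 0$ and $\gamma > 0$ the
likelihood is bounded away from 0 and 1, so mass can never vanish. Unit
tests verify five-trial posteriors against an independently coded
brute-force Bayes computation to 1e-10.

## Operating points: what the convergence simulations show

The package's headline simulations (`scripts/acceptance.R`) measure each
procedure's *operating point*: run the procedure against a simulated
observer, evaluate the observer's true $\Psi$ at each raw threshold
estimate, and average. Problem sizes were chosen as 500 runs per
procedure, which pins the mean to about ±1 percentage point.

For the Bayesian procedure with an observer identical to the assumed model
(threshold pen 8) the measured operating point is 80.0–80.3%, matching its
nominal 80% target; with more trials (60, 150) it tightens to 79.6–79.9%,
confirming the estimator converges to the target level.

For the staircase we use a shallow observer (slope 1 per pen,
$\lambda = 0$, threshold pen 8) and measure ≈64%, *below* the rule's
nominal $\sqrt{1/2} \approx 70.71\%$. This shortfall is a real property of
the protocol, not an estimation artifact, and it does not vanish with more
reversals (49 reversals: still ≈63%). Two mechanisms produce it. First,
the nominal value is the asymptotic target of the one-up/two-down rule on
a *continuous* stimulus axis; on the integer pen grid the chain's
equilibrium sits where the discrete up/down move probabilities balance —
between pen 8 ($\Psi = 0.80$) and pen 9 ($\Psi = 0.41$) for this observer,
at about pen 8.3, where $\Psi \approx 0.64$. Second, the Weibull is
asymmetric around the target (it saturates quickly toward strong stimuli),
so averaging $\Psi$ over the estimate's spread pulls the mean further
down. Users comparing the two procedures should therefore expect the
staircase to sit at a *weaker* stimulus level than its textbook 70.71%
on this discrete pen set — consistent with staircase thresholds running
higher (weaker pens) than Bayesian ones in cohort comparisons.

## Simulated observers and synthetic cohorts

`observer()` provides Weibull responders and pure guessers ($p = 1/3$
always). `generate_cohort()` emulates a two-session, two-procedure
test–retest study: per-participant true thresholds drawn from
$N(7, 3^2)$ pens (clipped to [1, 16]), a systematic retest sensitivity
gain of +1 pen, within-participant session drift $N(0, 2^2)$ pens, and
responses from the participant's Weibull observer (slope 3.5 per
log$_{10}$ unit, lapse 0.01). These defaults echo the scale of threshold
summaries reported for healthy adults with this instrument — means near
pen 7, between-participant SDs near 3, a retest gain near one pen, and
repeatability coefficients near 5–6 — but they are modelling conventions,
not estimates; every one is a `cohort_spec()` field.

What the generator deliberately does *not* model: adaptation and
habituation from repeated strong-pen presentations, attention drift within
a session, inter-session interval effects, and any dependence of the lapse
rate on fatigue. Tests that pass on these cohorts therefore validate the
*procedures and statistics*, not the physiology; in particular the
generator's clean Weibull observers understate the response instability
real participants show.

One spec-level property is untestable literally: with zero drift and zero
shift, test and retest runs are still not identical, because forced-choice
guessing is an irreducible per-trial noise source. The corresponding test
asserts the substance instead — identical true thresholds across sessions
and a vanishing mean test−retest difference.

## Cleaning and agreement statistics

`clean_threshold()` applies the boundary rules before any statistic:
staircase runs in which pen 1 was presented but never identified are set
to $T = 1$ (they would otherwise overestimate sensitivity, since the
protocol re-presents pen 1 until a hit allows it to continue); runs that
demanded a hypothetical pen 17 are set to $T = 16$; Bayesian estimates
outside [1, 16] are clamped. Cleaning is idempotent, and all reliability
statistics operate on cleaned values.

`repeatability()` computes $\bar d$, the sample SD of paired differences
($n-1$ denominator throughout), the repeatability coefficient
$RC = 1.96 \cdot SD$, and the Bland–Altman limits $\bar d \pm 1.96 \cdot
SD$. Confidence intervals for the limits use the exact-paired method: the
pivot $\sqrt{n}(\mu + 1.96\sigma - \bar d)/s$ follows a noncentral $t$
distribution with $n - 1$ df and noncentrality $1.96\sqrt{n}$, giving
exact two-sided intervals whose half-widths approach the familiar
$1.96\,s\sqrt{3/n}$ approximation for large $n$ (the approximation serves
as the cross-check oracle in the tests). Differences are oriented
test − retest within a procedure and staircase − QUEST between procedures.

For between-method comparisons through per-participant session means,
`corrected_loa()` restores the within-participant variance that averaging
removes: $\sigma_d^2 = s_{\bar d}^2 + \tfrac12 s_{xw}^2 + \tfrac12
s_{yw}^2$ with $s_{xw}^2 = \sum_i (x_{i1} - x_{i2})^2 / (2n)$, and limits
$\bar d \pm 1.96\,\sigma_d$. Corrected limits are never narrower than the
session-mean limits when within-variances are positive. Their confidence
intervals use a delta-method variance combining $\mathrm{Var}(\bar d)$
with the chi-square variances of the three components; we label these
approximate — unlike the exact-paired intervals for simple limits, no
exact pivot exists for the composite variance.

`reliability_report()` assembles the full analysis — paired Wilcoxon
signed-rank (R's `wilcox.test`, reporting the positive-rank sum $V$),
Spearman's $\rho$, an OLS fit of the second measurement on the first with
a Shapiro–Wilk residual check, descriptives, the agreement block, and (for
method comparisons) the corrected limits. `tdi_score()` sums threshold,
discrimination and identification scores; `estimate_duration()` converts
trial counts to minutes at 28.5 s/trial (20 trials ↦ 9.5 min exactly; note
that published trial-duration summaries round more coarsely, so converted
means can differ from printed durations by a few tenths of a minute).

## Known limitations

* The staircase's discrete-grid operating point depends on where the true
  threshold falls between pens; the ≈64% figure above is specific to an
  integer-pen threshold and a slope of 1 per pen.
* `load_deposited()` is a schema-mapping adapter for externally archived
  per-run records; it recognizes common column aliases and fails loudly
  otherwise. It never downloads anything, and the package's tests exercise
  it only on synthetic files in that layout.
* The corrected-limit confidence intervals are delta-method approximations
  and become unstable for very small $n$.
* Slope, guess and lapse are never estimated — both procedures treat the
  psychometric shape as known and estimate location only.
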