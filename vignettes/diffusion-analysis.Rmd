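---
title: "A diffusion-model pipeline for magnitude-comparison data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A diffusion-model pipeline for magnitude-comparison data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdiff)
```

## The scientific problem

In magnitude comparison (MC) a child decides which of two magnitudes is
larger — two Arabic numerals (symbolic MC) or two dot arrays
(non-symbolic MC). Response times and error rates in these tasks are
the workhorse measures of numerical-cognition research on developmental
dyscalculia, but neither measure alone separates *ability* from
*response caution*: a slow subject may be weak or careful, an accurate
subject may be able or conservative. The drift-diffusion model resolves
this by modelling the joint distribution of choices and response times
as noisy evidence accumulation between two absorbing boundaries.

`mcdiff` implements the full analysis chain for this design: the model
mathematics, trial-level cleaning, per-subject estimation, Weber-fraction
psychophysics for the dot task, the inferential layer (reliability,
adjusted correlations, dependent-correlation tests, effect sizes, Welch
tests, a mixed ANOVA), and a synthetic cohort generator so that every
stage is testable without access to raw study data.

## The model

A trial's response time decomposes as $T = T_d + T_{er}$: decision time
plus non-decision time (encoding, motor execution). The decision process
is a Wiener diffusion with unit diffusion coefficient between absorbing
boundaries $0$ and $a$, starting unbiased at $a/2$, with mean drift $v$
toward the correct boundary. Four parameters are estimated per subject
and task:

* `a` — boundary separation: response caution; raising it increases both
  accuracy and RT.
* `v` — mean drift rate: ability; raising it increases accuracy and
  decreases RT.
* `t0` — mean non-decision time (seconds).
* `st0` — the width of a uniform inter-trial window for non-decision
  time, $T_{er} \sim U(t_0 - s_{t_0}/2,\; t_0 + s_{t_0}/2)$; a cheap
  guard against contaminant RTs.

Under this parameterisation the probability of a correct response is
$P = e^{av}/(1 + e^{av})$, a function of the product $av$ alone, and the
expected decision time is $(a/2v)\tanh(av/2)$ with the drift-free limit
$a^2/4$. (A widely circulated printed form of the expected-decision-time
formula, $\frac{a}{2v}\frac{1-e^{av}}{1+e^{av}}$, is negative for
positive $a, v$; the `tanh` form used here is the sign-consistent
equivalent and matches the $v \to 0$ limit.) Start-point bias and
inter-trial variability of drift and start point are deliberately out of
scope: they need thousands of trials per subject to estimate and add
nothing at the few dozen trials typical of child studies.

First-passage-time densities and distributions use the two classical
series (image expansion for small scaled time $\tau = t/a^2$,
eigenfunction expansion for large $\tau$) with a crossover at
$\tau = 0.12$ and adaptive truncation once the term envelope falls below
$10^{-13}$; both branches agree with numerical quadrature of each other
to better than $10^{-8}$ in the test suite. Convolution with the uniform
non-decision window is a 12-node Gauss–Legendre average of the
decision-time CDF over the (clamped) window, exact to about $2\times
10^{-6}$ against a 32-node reference; `st0 = 0` degenerates to a pure
shift.

## Estimation

Each subject–task cell is fitted by minimising the Kolmogorov–Smirnov
distance between the model's and the empirical *signed* RT
distribution: error responses are placed at $-t$, correct responses at
$+t$, so a single supremum distance couples accuracy and the two RT
distributions. The supremum is evaluated at both one-sided limits of
every empirical jump point. This objective is robust to outliers and,
unlike maximum likelihood, does not acquire a boundary-separation bias
that depends on trial count — which matters here because the symbolic
and non-symbolic tasks have different numbers of items.

Search details, all of which were design decisions of this package:

* **Starting values.** A closed-form EZ-style inversion of accuracy and
  the mean/variance of correct RTs gives `a`, `v`, `t0`; `st0` starts at
  `0.3 * t0`. Accuracies of exactly 0, 1 or 0.5 are edge-corrected
  before the logit.
* **Optimiser.** Five Nelder–Mead starts (EZ plus four seeded
  perturbations). Each start iterates *re-centred* simplex runs from its
  current best point until the objective stops improving: the KS surface
  has a narrow curved valley in the $(a, v)$ plane (the product $av$ is
  pinned by accuracy long before the two factors separate), and a single
  simplex run with default initial steps reliably stalls in it.
  Objective tolerance `1e-5`.
* **Bounds.** $a \in [0.2, 4]$ and $v \in [-6, 6]$, generous covers of
  values seen in children's MC. The non-decision component is bounded
  through the *window edge* $e = t_0 - s_{t_0}/2 \in [0.025,\ \min rt]$
  and half-width $h = s_{t_0}/2 \in [0, 1]$, rather than by bounding
  $t_0$ itself with the fastest response. The distinction matters: with
  a non-degenerate window the earliest feasible RT is $t_0 - s_{t_0}/2$,
  so the true $t_0$ frequently *exceeds* the minimum observed RT, and a
  `t0 <= min(rt)` box excludes the optimum (in simulation it inflated
  `a` by ~0.4 before the re-parameterisation).
* **Quantile inversion** (for predicted quartiles) is bracketing plus
  bisection to $10^{-6}$ s. Because published fit plots do not always
  state whether RT quartiles pool both response types, both conventions
  are available (`mode = "all"` pools, `mode = "correct"` restricts).

The simulator is Euler–Maruyama at `dt = 1e-4` s with a Brownian-bridge
crossing correction each step (the probability that the path crossed a
boundary within a step despite interior endpoints is
$e^{-2 d_0 d_1/\Delta t}$); the correction removes the
$O(\sqrt{\Delta t})$ overshoot bias, leaving accuracy and mean-RT biases
an order of magnitude below Monte-Carlo noise at $n = 10^5$, which the
test suite checks against the closed forms.

## Cleaning rules

Practice removal, cut-offs and exclusion mirror standard practice for
this design: the first symbolic test item and the first three
non-symbolic test items are treated as additional practice (leaving 23
and 45 analysable items); responses faster than 250 ms or slower than
4 s are discarded, with *strict* inequalities so a response at exactly
the cut-off is kept; and a subject is excluded entirely when more than
half of either task's post-practice items fall outside the window. The
ordering — practice removal first, exclusion denominators from
post-practice counts — is a documented package decision, as sources for
this design do not pin it down. Missing measures (a subject with no
correct trials) propagate as `NA` and are dropped pairwise per analysis.

## Weber fractions

Non-symbolic precision is summarised by the Weber fraction $w$ under the
linear approximate-number-system model: dot sets of sizes $n_1, n_2$ are
represented as Gaussians with SDs $w n_i$, giving
$P(\text{correct}) = \Phi\!\big(|n_1 - n_2| / (w\sqrt{n_1^2 +
n_2^2})\big)$. The exact formula variant is a package decision (the
common erfc form of the Panamath literature). $w$ is estimated by
Bernoulli maximum likelihood on $[0, 3]$ — a 0.005-step grid followed by
golden-section refinement — with boundary optima flagged: all-correct
data push $w \to 0$, chance-level data to the cap at 3.

Two estimator properties worth knowing: on 45-trial data the MLE is
right-skewed (the cap turns low-accuracy samples into a point mass near
3), so its *median* is centred on the truth while its mean sits above
it; and because fitted $w$ is nearly a monotone transform of observed
accuracy, the two are very strongly rank-correlated (Spearman about
−0.97 in simulation) while the *Pearson* correlation is flattened to
about −0.8 by the saturating accuracy curve and the cap.

## The synthetic cohort generator

The generator encodes the study conditions the analysis is designed
for; its defaults are fixed and are not tuning knobs:

* Two groups — 272 control, 81 dyscalculic — with per-task diffusion
  parameters drawn from group-specific normals truncated to valid
  ranges (means/SDs as in `default_population_config()`), e.g. control
  symbolic $v$: 2.44 (0.90) versus dyscalculic 1.92 (0.62).
* Item designs: 24 symbolic test items with each numeral distance 1–6
  appearing exactly four times (plus 3 practice items), and 48 dot items
  — twelve per ratio bin 1.2/1.4/1.6/2.6, counts 5–21, half
  size-controlled (plus 2 practice items).
* A standard-normal latent achievement factor per subject loads
  positively on drift (0.35 both tasks) and negatively on boundary
  separation (−0.30 symbolic, −0.05 non-symbolic), with smaller negative
  loadings on the non-decision parameters, inducing
  achievement–parameter correlations of realistic magnitude (about
  0.2–0.3 before attenuation). The loadings are documented defaults,
  not estimates of the original study's values.
* The same parameter correlates 0.5 across tasks within subject — a
  documented placeholder, as no source quantifies this covariance.
* Non-symbolic item difficulty scales the subject's drift by
  $\log(\text{ratio})$, normalised so the configured $v$ is the
  design-average drift; estimation still fits a single $v$ per cell,
  matching how such data are analysed.
* Contaminants: 1.01% fast guesses (uniform 0.05–0.25 s, correctness
  re-drawn at chance) and 1.25% slow outliers (uniform 4–8 s), the rates
  the cleaning stage is designed around.

What the generator does *not* emulate: fatigue, post-error slowing,
sequential effects, pixel-level stimulus control, or any drift
dependence on numeral distance in the symbolic task. Passing tests on
synthetic cohorts therefore demonstrate that the estimation and
inference machinery is correct and well-calibrated under the stated
model — not that the model is true of real children.

## Problem sizes used in the checks

The packaged checks run at sizes chosen to exercise every claim while
staying desk-scale: simulator-versus-closed-form agreement at
$n = 10^5$ trials over 20 randomised parameter sets; large-sample
parameter recovery on 5,000 trials at the control-group symbolic means
(tolerances ±0.1 on $a$ and $v$, ±0.02 s on $t_0$); study-scale
recovery at 23/45 trials across 50 synthetic subjects (recovery
correlations above 0.5 for $a$ and $v$, above 0.8 for $t_0$, with $t_0$
the most reliable, matching the published split-half ordering); and
three cohort replicates at 150 control/45 dyscalculic subjects for the
group-comparison sign pattern (effect sizes averaged over replicates —
the weakest attenuated effect has a per-replicate sampling SE of ~0.17)
and the ANOVA group effect on drift (required in at least two of the
three replicates).
Cohort-scale fits use a slightly lighter optimiser setting
(`reltol 1e-4`, fewer restarts) than single-subject work; single-cell
estimates are unchanged to well within sampling error.

## Known limitations

* The KS estimator is consistent but not efficient; at 23 items the
  drift-rate reliability is intrinsically modest (the published
  split-half values, 0.42–0.60 for $v$, set realistic expectations).
* Boundary-flagged Weber fits (about a fifth of subjects at realistic
  noise levels) carry little individual information; group-level
  analyses should treat $w = 3$ values as censored rather than exact.
* The mixed ANOVA reports classical $\eta^2$ (`SS_effect/SS_total`) as
  primary — consistent with small published effect sizes computed
  against total variance — and partial $\eta^2$ alongside; which variant
  a given paper reports is often unstated.
* Williams' $t$ (df $= n - 3$) is used for comparing dependent
  correlations; variants (e.g. Steiger's) differ slightly in small
  samples.
* The confidence interval for Cohen's $d$ uses the large-sample normal
  standard error $\sqrt{(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))}$, which
  reproduces published two-decimal bounds at these group sizes;
  noncentral-$t$ inversion would differ in the third decimal.

## A worked example

```{r example, eval = FALSE}
library(mcdiff)

cfg <- default_population_config()
cfg$groups$con$n <- 60     # scaled-down cohort for illustration
cfg$groups$dys$n <- 20

report <- run_study(config = cfg, seed = 1, reliability = FALSE)
print(report)

# effect sizes straight from summary statistics
cohens_d(2.44, 0.90, 272, 1.92, 0.62, 81)   # d = 0.62, CI [0.36, 0.87]
```

The report bundles the filter bookkeeping, the per-subject summary
(accuracy, median correct RT, fitted `a`, `v`, `t0`, `st0`, Weber
fraction), the reliability, correlation, group-comparison and ANOVA
tables, and a provenance block (seed, package version, full generator
configuration) sufficient to regenerate the run byte-for-byte.
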