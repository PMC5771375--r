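# mcdiff

Diffusion-model analysis of symbolic and non-symbolic magnitude
comparison.

## What this is for

Magnitude-comparison tasks — "which of two numerals is larger?", "which
dot array has more dots?" — are the standard probes of basic number
processing in research on developmental dyscalculia. Their raw measures,
response time and accuracy, confound *ability* with *response caution*:
a child can be slow because comparison is hard or because they are
careful. `mcdiff` implements the drift-diffusion decomposition of such
data for researchers in numerical cognition and psychometrics: the joint
choice/RT distribution is modelled as noisy evidence accumulation
between two boundaries, yielding per-subject estimates of ability (drift
rate `v`), caution (boundary separation `a`) and non-decision time
(`t0`, with uniform inter-trial range `st0`).

The core model is the unbiased four-parameter Wiener diffusion (start
`a/2`, unit diffusion coefficient), under which

    P(correct) = exp(a v) / (1 + exp(a v))
    E(decision time) = (a / 2v) * tanh(a v / 2)

Estimation minimises the Kolmogorov–Smirnov distance between the model
and empirical *signed* RT distributions (errors at `-t`, corrects at
`+t`) — robust to contaminant RTs and free of the trial-count-dependent
bias that maximum likelihood imposes on `a`. Around the core the package
provides trial cleaning (250 ms / 4 s cut-offs, practice-item removal,
subject exclusion), Weber-fraction estimation for dot comparison
(maximum likelihood on [0, 3] under the linear ANS model), split-half
reliability with Spearman–Brown correction, correlations with
achievement scores under Bonferroni–Holm control, Williams' test for
dependent correlations, pooled Cohen's d with confidence intervals,
Welch tests, a 2×2 mixed ANOVA (group × task), and a synthetic cohort
generator that reproduces the study conditions (272 control / 81
dyscalculic subjects, 24-item symbolic and 48-item dot designs) so the
whole pipeline runs and is tested without any raw data.

## A worked example

```r
library(mcdiff)

# effect size straight from group summary statistics (n = 272 / 81)
cohens_d(2.44, 0.90, 272, 1.92, 0.62, 81)
#> $d        0.6158
#> $ci_low   0.3636
#> $ci_up    0.8680
# printed to two decimals: d = 0.62, CI [0.36, 0.87] - the control
# group's symbolic drift advantage over the dyscalculic group

# a scaled-down synthetic study, end to end (~2 min)
cfg <- default_population_config()
cfg$groups$con$n <- 60; cfg$groups$dys$n <- 20
report <- run_study(config = cfg, seed = 42, reliability = FALSE,
                    fit_control = list(reltol = 1e-4, maxit = 250))
print(report)
#> trial filter report
#>   input responses:        5760
#>   practice items removed: 320
#>   fast responses removed: 58 (1.07%)
#>   slow responses removed: 80 (1.47%)
#>   subjects excluded:      0
#> subjects summarised: 80
#>
#> group comparison (d with CI, Holm-adjusted p):
#>         task   measure     d             ci  p_holm
#>  nonsymbolic         v  0.43  [-0.09, 0.94] 0.73000
#>  nonsymbolic median_rt -1.71 [-2.28, -1.14] 0.00029
#>     symbolic         v  0.57   [0.06, 1.09] 0.12000
#>     symbolic median_rt -0.86 [-1.39, -0.34] 0.01500
#>  ...
#> mixed ANOVA on v:
#>      effect         F            p        eta2
#>       group  5.901587 1.742696e-02 0.031069305
#>        task 94.938845 3.928720e-15 0.302767456
#>  group:task  2.125634 1.488676e-01 0.006778814
```

The control group's drift advantage (`d > 0` for `v`, both tasks) and
the dyscalculic group's slower median RTs come through already at this
scale; the group effect on `v` is significant in the mixed ANOVA
(F = 5.9, p = 0.017, classical eta squared 0.031), while the
group-by-task interaction needs the full cohort size for power.

Per-subject fitting:

```r
set.seed(1)
trials <- simulate_trials(500, diffusion_params(1.5, 2.44, 0.73, 0.23))
trials$rt_s <- trials$rt
fit <- fit_subject_task(trials)
print(fit)
#> diffusion fit (KS): a=1.390 v=2.264 t0=0.752 st0=0.213 | D=0.0133 n=500
```

A thin command-line wrapper with `simulate` / `fit` / `report` / `run`
subcommands lives at `inst/cli/mcdiff.R`.

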