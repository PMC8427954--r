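---
title: "Ordinal sigmoid-Emax pharmacodynamics of propofol sedation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal sigmoid-Emax pharmacodynamics of propofol sedation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umsspd)
```

## The model and its assumptions

Sedation depth on the University of Michigan Sedation Scale (UMSS; 0
awake/alert, 1 minimally sedated, 2 moderately sedated, 3 deeply sedated, 4
unarousable) is related to the effect-site concentration $C_e$ of propofol
through four threshold ("response") probabilities, each a sigmoid Emax
curve with a shared Hill coefficient:

$$P(\mathrm{UMSS} \ge n) \;=\; \frac{C_e^{\gamma}}{C_{e50,n}^{\gamma} + C_e^{\gamma}}, \qquad n = 1,\dots,4 .$$

$C_{e50,n}$ is the steady-state concentration at which sedation of depth at
least $n$ has probability one half; sharing $\gamma$ across thresholds keeps
the four curves parallel on the log-concentration scale, which both
stabilizes estimation and guarantees that the threshold probabilities never
cross (deeper sedation is never more probable than lighter sedation at any
concentration). The probability of observing *exactly* score $n$ is taken
as the product of responses up to $n$ and non-responses above $n$ (with
$P(\mathrm{UMSS}\ge 0)\equiv 1$):

$$P(\mathrm{UMSS}=n) \;=\; \prod_{k \le n} P(\mathrm{UMSS}\ge k)\,
  \prod_{k>n} \bigl(1 - P(\mathrm{UMSS}\ge k)\bigr),$$

and the predicted score at a given $C_e$ is the score with the highest such
probability, ties (a measure-zero event that does occur exactly at
$C_e = C_{e50,n}$) resolving to the lower score so that the prediction is
deterministic and conservative about sedation depth.

Two properties of this construction deserve explicit statement because they
drive several design choices below.

**The product formula is sub-stochastic.** The five products do not sum
to 1 except in degenerate limits (at $C_e=3$ with the reference parameters
the sum is about 0.857). `category_probs()` therefore returns the raw
products by default — these are what the pooled likelihood factorizes into —
and offers `normalize = TRUE` when a proper categorical distribution over
scores is wanted. The most probable score is the same either way.

**The crossover identity.** The ratio of adjacent category products is
$P(\mathrm{UMSS}=n)/P(\mathrm{UMSS}=n-1) = q_n/(1-q_n)$ with
$q_n = P(\mathrm{UMSS}\ge n)$, which passes one exactly at
$C_e = C_{e50,n}$. The most-probable score therefore steps from $n-1$ to
$n$ exactly at $C_{e50,n}$, and on a 0.1-ug/mL presentation grid each
interval starts at the first grid value strictly above the corresponding
$C_{e50}$ (`score_breakpoints()`).

## Estimation

Each observation is expanded to four binary records ($R=1$ if the observed
score is at or above the threshold), and all subjects are pooled with
inter-individual variability fixed to zero — under which the Laplacian
objective of mixed-effects software reduces to the plain product of
Bernoulli likelihoods $L = R\,P + (1-R)(1-P)$. The product of one
observation's four terms equals its category product, so the binary
expansion and the ordinal formulation give the same likelihood; the package
asserts this identity to $10^{-12}$ in its tests.

`fit_mle()` maximizes this likelihood by BFGS with an analytic gradient on
the parameterization $(\log c_1, \log(c_2-c_1), \log(c_3-c_2),
\log(c_4-c_3), \log\gamma)$, which enforces positivity and the strict
threshold ordering smoothly. Five starts (an empirical initial value plus
jittered copies; deterministic seed) guard against local optima; the
objective tolerance is $10^{-10}$ (relative). Probabilities are clamped to
$[10^{-12}, 1-10^{-12}]$ inside the logarithm only, and clamp events are
counted and reported. Standard errors come from the inverse of a
central-finite-difference Hessian (relative step $10^{-4}$) on the natural
scale; 95% confidence intervals are Wald intervals
$\hat\theta \pm 1.96\,\mathrm{SE}$, whose printed-table arithmetic
(`estimate * (1 +/- 1.96 RSE/100)`) is exposed as `wald_ci()`.

## Validation tools

*Bootstrap.* `bootstrap_ci()` resamples subjects with replacement (equal
number of individuals; duplicated subjects get fresh identifiers so the
refit treats them as distinct), refits each replicate warm-started from the
original estimates, and reports the 2.5–97.5 percentiles. Failed or
non-converged replicates are excluded and counted, with a warning beyond
20%.

*Prediction probability.* $P_k = (\text{Somers' } d + 1)/2$ for the
predictor given the outcome: over observation pairs with distinct observed
scores, concordant pairs count 1, predictor-tied pairs 1/2, discordant 0.
Pairs tied on the *observed* score are excluded; this tie convention is
what makes the pair-counting form $(C + T/2)/(C+D+T)$ coincide with the
Somers' d definition and is the standard convention in the anesthesia
literature. The confidence interval is a delete-one jackknife with normal
approximation by default (the classical choice; the source analysis does
not state its method), with an observation-bootstrap percentile interval as
an alternative. Both are deterministic given a seed.

*Bland–Altman.* `bland_altman_percent()` uses percent differences relative
to the pairwise mean — the standard percent Bland–Altman; the denominator
choice is not stated in the source analysis, so exact reproduction of its
printed biases is not claimed — reporting bias, 95% limits of agreement
(bias ± 1.96 SD) and a bias CI (± 1.96 SD/√n).

## The simulator and the synthetic study

The PK side is the standard mammillary three-compartment model with an
effect compartment ($dC_e/dt = k_{e0}(C_p - C_e)$), solved per interval by
matrix exponentials — exact for piecewise-constant infusion — and verified
against a fine-step Runge–Kutta reference to $10^{-6}$ relative error. The
TCI controller is deliberately idealized: per 1-s tick it infuses at the
largest rate that keeps predicted plasma below 4x the current target,
throttles the final tick so that the predicted zero-input $C_e$ peak lands
on the target (a few secant iterations on the peak-vs-rate map), and then
retargets $C_e$ each tick. A target counts as reached when $|C_e -
\text{target}| \le 0.02$ ug/mL on two consecutive ticks and is then held
for 2 min. Any controller achieving the $C_e$ staircase is equivalent for
the pharmacodynamic analysis.

The default study design reproduces the source protocol: effect-site
targets 1 to 6 ug/mL in 1-ug/mL steps, 2-min holds, UMSS assessed every
20 s, 30 subjects, and the published point estimates
($C_{e50} = 1.84, 2.64, 3.98, 4.78$ ug/mL, $\gamma = 5.76$) as generating
truth. The default PK parameter set is *synthetic* (plausible constants for
a ~19-kg child; clearance 0.76 L/min, $V_1$ 9.5 L, $k_{e0}$ 0.8 /min): the
pump model actually used in the clinical study is published elsewhere and
its constants must be supplied by the user for any real concentration
comparison.

The clinical analysis kept only 8–10 points per subject: the start of
infusion, the first observation of each score increment, a midpoint of each
maintained-score period for scores 0–3 (snapped down to the 20-s assessment
grid, since selected points must be actual observations), and the
observation 20 s after score 4 was reached. `select_modeling_points()`
implements exactly this rule.

### Why the "independent" mode uses a fixed sampling design

The generator offers two sampling modes. `"monotone"` emulates a real
induction: the running maximum of independent categorical draws, stop one
assessment after the observed score reaches 4, and the selection rule
applied to the observed scores — exactly the clinical procedure. Pooled
estimation on such data is *biased by construction* (the running maximum
changes the marginal response probabilities), which the generator records
in the dataset's `mode` attribute so the two worlds are never silently
mixed.

`"independent"` mode exists to verify the estimator against its own
assumptions: scores are drawn i.i.d. at each time point. Three choices in
this mode required care:

1. **What distribution to sample.** Drawing from the *normalized* product
   formula distorts the exceedance probabilities — under it
   $P(\text{score} \ge n)$ is no longer the sigmoid $q_n$ — and measurably
   biases the pooled fit (about +33% in $\gamma$ at 500 full-grid
   subjects). `sample_umss()` therefore draws from the cumulative ordinal
   distribution $P(\mathrm{UMSS}=n) = q_n - q_{n+1}$ (exposed as
   `score_distribution()`), under which the four threshold indicators have
   exactly the sigmoid marginals the likelihood assumes.

2. **Selection must be ancillary.** Applying the "first time the score
   reaches $n$" rule to i.i.d. draws selects extreme early chance successes
   and biased the Ce50s by −16% to −26% in direct measurement. In
   independent mode the selection times are therefore computed once from
   the model-*predicted* score staircase — the same at most 10 times for
   every subject, an outcome-independent design of the same shape and
   density as the clinical rule.

3. **Stopping must not empty the top threshold.** Stopping at the first
   i.i.d.-sampled 4 stops most subjects near $C_e \approx 3$ (a flicker
   artifact), leaving $C_{e50,4}$ weakly or non-identifiable in 30-subject
   studies and breaking about 40% of bootstrap replicates. Independent mode
   therefore runs the full fixed design (ending 20 s after the *predicted*
   score reaches 4); the outcome-dependent stop rule belongs to
   `"monotone"` mode, where it is the clinical procedure. (An adapted stop
   rule does not bias the likelihood — measured at under 1% — it only
   destroys information in the flicker regime.)

With these choices the pipeline is self-consistent: a 500-subject study
refit recovers every generating parameter within a few percent, which is
the package's core end-to-end acceptance property.

### What a green simulation test does not establish

The generator emulates the *design* of the source study, not its data. Real
sedation scores are serially correlated, monotone during induction, and
rater-dependent; real concentration time courses come from a specific pump
model whose parameters this package does not ship; and the published
dataset itself is not public. Green tests therefore establish that the
estimator, bootstrap, Pk and agreement machinery are correct under the
model's own assumptions and design — not that the published parameter
values are re-derivable from raw clinical data, and not that the
published Pk (0.770) or Bland–Altman biases are reproducible (they depend
on the unreleased infusion logs).

## Numerical choices

* Sigmoid probabilities are computed in log space
  (`plogis(gamma * (log ce - log ce50))`), so Hill coefficients in the
  hundreds do not overflow; $C_e = 0$ maps to probability exactly 0 and
  $C_e = C_{e50}$ to exactly 0.5.
* The optimizer's increment floor ($10^{-9}$, plus a relative
  $1+10^{-12}$ guard) keeps threshold ordering strict in floating point at
  extreme excursions.
* The matrix-exponential step operators are computed once per step size;
  the steady-state approach of the PK system is governed by its slowest
  eigenvalue (about 0.0023 /min for the synthetic set — the terminal
  redistribution phase), which the tests use when asserting the
  constant-infusion limit $C_p \to r/(V_1 k_{10})$.
* Bootstrap percentiles use the default quantile definition (type 7);
  jackknife Pk intervals are truncated to $[0,1]$.
* All stochastic routines take explicit seeds; the default seed 20210909
  is recorded in outputs.

## Known limitations

* No inter-individual random effects and no covariate (age/weight) effects
  on $C_{e50}$ or $\gamma$ — deliberately, matching the source analysis.
* The pooled Hessian-based standard errors treat the four binary records of
  an observation as independent, as the source software does; they are not
  robust ("sandwich") errors.
* The symmetric natural-scale Wald interval — retained because it is the
  published table's arithmetic — undercovers for $\gamma$ at the 30-subject
  design (measured 87% over 1000 simulated studies, versus 94–95% for the
  $C_{e50}$s): $\gamma$'s sampling distribution is right-skewed, the
  classic argument for log-scale or profile intervals. The bootstrap
  percentile intervals do not share this defect (92–94% coverage for all
  five parameters).
* The TCI controller is an idealization; it reproduces the $C_e$ staircase
  but not the transient behaviour of any commercial pump.
* Config files are JSON only (no YAML parser among the package's
  dependencies).
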