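---
title: "MR-LOVA: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MR-LOVA: model, algorithm, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrlova)
```

## The causal model and the latent outcome

Two-sample Mendelian randomization (MR) estimates the causal effect
$\tau$ of an exposure $c$ on an outcome $y$ using genetic variants as
instruments. The working model is

$$c = Xb + \epsilon, \qquad y = c\tau + Xu + e,$$

where $X$ holds genotype dosages, $b$ the SNP effects on the exposure and
$u$ the *direct* (horizontal-pleiotropy) SNP effects on the outcome. A
variant is a valid instrument when it is associated with the exposure
(relevance) and has $u_j = 0$ (exclusion restriction). The marginal
outcome association of SNP $j$ is $g_j = b_j\tau + u_j$: vertical
pleiotropy ($b_j\tau$) is the signal MR estimates from, horizontal
pleiotropy ($u_j$) the bias it must remove.

If $\tau$ were known, the latent outcome

$$\upsilon = y - c\tau = Xu + e$$

would contain *only* horizontal pleiotropy, and a GWAS of $\upsilon$
would reveal exactly which variants violate the exclusion restriction.
Since $\tau$ is unknown, `mr_lova()` runs a stochastic EM algorithm that
imputes the latent quantities instead of marginalizing them:

1. **Initialize** $\tau^{(0)} = 0$. Starting from "no causal effect"
   keeps the algorithm from being drawn toward spurious solutions when
   many instruments are invalid; a different starting value can be given
   via `tau0` when strong prior knowledge exists.
2. **E-step.** With column-standardized genotypes and standardized
   summary effects ($\hat b_j, \hat g_j$, each with sampling variance
   $1/n$), the direct effects are imputed as
   $\hat u_j^{(t+1)} = \hat g_j - \tau^{(t)}\hat b_j$ with variance
   $\mathrm{var}(\hat u_j^{(t+1)}) = \mathrm{var}(\hat g_j) +
   (\tau^2 - 2\tau\,\mathrm{cov}(y,c))/n$, where
   $\mathrm{var}(\upsilon) = 1 + \tau^2 - 2\tau\,\mathrm{cov}(y,c)$ on
   the standardized scale.
3. **Selection.** The inclusion indicator is $I_j = 1$ iff the latent
   outcome shows no direct effect (two-sided normal p-value of
   $\hat u_j$ above `p_outcome`, default 0.05) *and* the exposure effect
   is genome-wide significant (p-value of $\hat b_j$ below `p_exposure`,
   default $5\times 10^{-8}$).
4. **M-step.** Inverse-variance-weighted regression of $\hat u$ on
   $\hat b$ over the included instruments,
   $$\Delta\tau = \frac{\sum_j I_j \hat u_j \hat b_j\,
   \mathrm{se}(\hat u_j)^{-2}}{\sum_j I_j \hat b_j^2\,
   \mathrm{se}(\hat u_j)^{-2}},$$
   followed by $\tau^{(t+1)} = \tau^{(t)} + \Delta\tau$.
5. Repeat 2--4 until $|\Delta\tau| < 10^{-6}$ (at most 100 iterations;
   non-convergence is flagged, not thrown).

At convergence $\mathrm{se}(\hat\tau) = (\sum_j I_j \hat b_j^2 /
\mathrm{var}(\hat u_j))^{-1/2}$ and the p-value uses the normal
reference.

### Why the additive M-step

Because $\hat u$ is already residualized on the current $\tau$, the IVW
ratio above estimates the *increment* still missing from $\tau$, so the
update must be additive. This makes the truth a fixed point: at
$\tau = \tau_{\text{true}}$ the imputed $\hat u$ of valid instruments is
pure noise and the expected increment is zero. The alternative reading --
regress $\hat g$ on $\hat b$ with the current $\mathrm{var}(\hat u)$
weights and replace $\tau$ -- shares that fixed point and is available as
`mstep = "direct"` for sensitivity analysis; the two agree at
convergence whenever they select the same instruments.

### Numerical choices

* $\mathrm{cov}(y, c)$ is approximated once (not per iteration) by the
  genetic covariance $\sum_j \hat g_j \hat b_j$ over the panel given to
  the fit, valid for approximately independent (clumped) standardized
  SNPs. It is clipped to $(-0.999, 0.999)$ so
  $\mathrm{var}(\upsilon) > 0$ for every $\tau$ the iteration can visit.
* $\mathrm{var}(\hat u_j)$ is floored at $10^{-12}$.
* If the inclusion set empties mid-iteration, that iteration falls back
  to relevance-only selection (logged) instead of aborting, so
  permutation refits cannot crash on an unlucky shuffle; an empty set at
  convergence is still an error.
* Standardization uses $z/\sqrt n$ and $\mathrm{se} = 1/\sqrt n$,
  ignoring the $z^2/n$ correction: the per-SNP variance explained is
  effectively zero for GWAS instruments, so
  $\mathrm{var}(\hat g_j) = 1/n$ holds to first order.
* All p-values are two-sided normal; no multiple-testing adjustment is
  applied inside the inclusion rule, which uses the fixed thresholds
  above.

### LD-adjusted and individual-level paths

When instruments are not fully independent, a reference-panel
correlation matrix $\Omega$ converts the marginal $\hat u$ into joint
multiple-regression coefficients $\Omega^{-1}\hat u$ with variances
$\mathrm{diag}[(n\Omega)^{-1}](\mathrm{var}(\upsilon) - R^2)$, where
$R^2 = \hat u'\Omega^{-1}\hat u$ is capped below
$\mathrm{var}(\upsilon)$. $\Omega$ gets a ridge of $10^{-3}$ on the
diagonal when its smallest eigenvalue falls below $10^{-6}$ (logged).
The adjusted $\hat u$ and variances feed both the inclusion rule and the
M-step. With $\Omega = I$ and negligible $R^2$ this path coincides with
the independent-SNP path.

`mr_lova_individual()` runs the same EM on raw cohorts: each iteration
forms $\upsilon = y - \hat c\,\tau$ in the outcome cohort -- with
$\hat c = X\hat b$ the genetic prediction of the exposure in the
two-sample design, or the observed exposure when `one_sample = TRUE` --
and re-estimates $\hat u_j$ by per-SNP regression. Since $\upsilon$ is
linear in $\tau$, these regressions are evaluated in closed form.

## Diagnostics

* `permutation_test()` shuffles the initial $(\hat u_j, \mathrm{se})$
  pairs -- which at $\tau^{(0)} = 0$ equal $(\hat g_j, \mathrm{se}(\hat
  g_j))$ -- against $\hat b$, re-runs the *complete* EM on every shuffle
  so that selection uncertainty propagates into the null, and reports
  $(1 + \#\{|\tau_{\text{perm}}| \ge |\hat\tau|\})/(B + 1)$ (never
  exactly zero). Re-running selection per shuffle is the more
  conservative of the two possible designs. Note one structural
  property: when all instrument strengths share a sign (as with
  left-truncated strengths) and the outcome effects are proportional to
  them, the shuffled through-origin slope stays near
  $\tau\,\bar b^2/\overline{b^2}$ rather than zero, so the permutation
  null is conservative under a true effect and costs some power --
  the trade-off for exactness under the no-relationship null.
* `directional_pleiotropy_test()` is a one-sample t-test of
  $\mathrm{mean}(u) = 0$; `inside_test()` is a Pearson correlation test
  of $\mathrm{cor}(u, b) = 0$ (InSIDE: Instrument Strength Independent
  of Direct Effect). `mr_diagnostics()` evaluates both on $\hat u$ at
  the converged $\hat\tau$ over *all* instruments in the panel, not only
  the selected ones: the excluded instruments carry exactly the
  pleiotropy signal the tests look for. (Which set to use is genuinely
  open; restricting to selected instruments would test a censored,
  near-null sample.)
* `mr_ivw()` (fixed-effect, through the origin) and `mr_egger()`
  (weighted with intercept) are intentionally minimal internal baselines.

## The simulator

`sim_config()` / `run_experiment()` generate two-sample GWAS data from

$$z = X\varphi + \eta,\quad c = Xb + z + \epsilon,\quad
  y = c\tau + Xu + z + e,$$

with $X_{ij} \sim \mathrm{Binomial}(2, f_j)$, $f_j \sim U(0.1, 0.3)$,
and $\eta, \epsilon, e \sim N(0,1)$. The unobserved confounder $z$ is
present in **every** scenario (with $\varphi = 0$ it is the shared
non-genetic confounder $\eta$, inducing $\mathrm{cov}(c, y) \approx 1$
even under the null -- which MR, unlike observational regression, must
shrug off). Instrument strengths come from a left-truncated normal:
$N(0, 0.1)$ truncated at $0.1$ for 30-instrument panels, $N(0, 0.05)$
truncated at $0.05$ for 100-instrument panels, sampled by rejection.

The four scenarios assign the invalid subset
(`round(prop_invalid * m)` SNPs):

| scenario | direct effects $u$ | confounder loadings $\varphi$ | InSIDE |
|---|---|---|---|
| 1 `no_pleiotropy` | $0$ | $0$ | holds |
| 2 `balanced` | $N(0, 0.15)$ | $0$ | holds |
| 3 `directional` | $N(0.1, 0.075)$ | $0$ | holds |
| 4 `inside_violated` | $N(0.1, 0.075)$ | $U(0, \theta)$ | violated |

Distribution parameters $N(a, b)$ read $b$ as a *standard deviation*
(scenario 3 is then strongly directional, mean/sd $\approx 1.3$, which
matches its intended character); `pleio_scale = "var"` switches the
reading. In scenario 4 the $u$ and $\varphi$ supports coincide -- the
sterner InSIDE violation, since every pleiotropic variant is also a
confounder path. MAFs and true effects are redrawn each replicate and
shared between a replicate's two (disjoint) cohorts; one master seed
spawns a recorded per-replicate seed stream, so a `MetricsTable` is
bit-reproducible from `(config, seed)`.

`tau_scaled` is the causal effect between standardized traits; the
raw-trait effect satisfies
$\tau_{\text{raw}} = \tau_{\text{scaled}}\,\mathrm{SD}(y)/\mathrm{SD}(c)$
and is found by fixed-point iteration on a pilot cohort of 10,000
(`calibrate_tau()`, tolerance $10^{-4}$), since $\mathrm{SD}(y)$ itself
depends on $\tau_{\text{raw}}$. Phenotypes are standardized within each
cohort before the per-SNP regressions, so summary effects arrive on the
standardized scale the EM derivation assumes.

By default `run_experiment()` hands **all** $m$ instruments to every
estimator (`p_exposure = 1`), matching the reference evaluation design
in which each method receives the full instrument set and does its own
selection; with cohorts of 50,000 and the truncated-normal strengths,
a typical valid instrument has an exposure $z$-statistic near 4, so a
binding $5\times10^{-8}$ screen would discard most valid instruments
before the EM ever saw them. Set `p_exposure = 5e-8` to study the
screened regime instead.

### What the simulator does and does not emulate

It reproduces confounded, two-sample, standardized-trait GWAS with
independent biallelic SNPs. It does **not** model LD between
instruments, allele-frequency/effect-size coupling, binary outcomes,
sample overlap, population stratification, or winner's-curse selection
of instruments. Passing tests therefore demonstrate correct behavior
under the stated generative model, not robustness to those real-data
complications (LD is handled separately via the reference-panel path;
instruments are assumed pre-clumped, e.g. plink with $r^2 < 0.1$ in
500 kb windows).

## Problem sizes used in the checks

The packaged tests and `scripts/acceptance.R` evaluate the reference
conditions -- 100 instruments, cohorts of $n = 50{,}000$, 100 replicates
per condition -- for the selection operating characteristics (scenario
4, $\theta = 0.7$, 70% invalid), type-I error (scenario 1, $\tau = 0$),
and parameter recovery (scenario 1, $\tau_{\text{scaled}} = 0.2$).
Diagnostic calibration uses 1000 direct draws of $u$ (and $b$) per null;
permutation uniformity uses 200 small synthetic panels with $B = 99$
permutations each. Unit oracles (normal-equation solves, identity
reductions, closed-form regressions) run at toy sizes.

## Known limitations

* The $\mathrm{cov}(y, c)$ approximation ignores the non-genetic share
  of the phenotypic covariance; its influence is confined to the
  $O(\tau/n)$ variance correction, but extremely confounded traits with
  few instruments could misestimate $\mathrm{var}(\hat u)$ slightly.
* The permutation test re-runs the full EM $B$ times; at $B = 1000$ and
  hundreds of instruments this is the dominant cost of a fit.
* Weak instruments are handled only through the relevance threshold;
  no overlapping-sample or binary-outcome (logistic-scale) corrections
  are applied.
* Harmonization matches on identifier and allele pair only: strand
  flips beyond the palindromic flag, INDELs, and genome-build liftover
  are assumed resolved upstream. Whether palindromic SNPs should be
  dropped is exposed as `drop_palindromic` (default off).
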