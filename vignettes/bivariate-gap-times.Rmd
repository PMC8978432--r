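---
title: "Methods for bivariate alternating recurrent gap times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods for bivariate alternating recurrent gap times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The data structure

Subjects in a longitudinal study alternate between two states — say care
periods and break periods in a psychiatric case register, or hospitalization
and community time after a chronic-disease diagnosis. Episode $j$ of subject
$i$ is the pair $(X^0_{ij}, Y^0_{ij})$ of a Type I gap (first state) and the
Type II gap (second state) that follows it. Follow-up ends at a censoring
time $C_i$, so subject $i$ contributes $m_i$ episodes with
$$\sum_{j \le m_i - 1}(X^0_{ij} + Y^0_{ij}) \le C_i <
  \sum_{j \le m_i}(X^0_{ij} + Y^0_{ij}).$$
Episodes before the last are fully observed; in episode $m_i$ the Type I gap
may be cut at the residual follow-up
$C^*_{im_i} = C_i - \sum_{l < m_i}(X^0_{il}+Y^0_{il})$, and the Type II gap
is always censored. Two features make naive analyses wrong here:

* **informative episode counts** — subjects with short gaps accumulate more
  episodes before $C_i$, so pooling episodes over-represents fast cyclers;
* **induced dependent censoring** — the Type II gap is censored at
  $C^*_{ij} - X_{ij}$, which depends on the Type I gap preceding it, so the
  Type II marginal distribution is not identifiable at all.

`episode_table()` ingests the long format (one row per episode, baseline
covariates repeated) and enforces the structural rules; any violation raises
an error beginning with `"Error: Data not cleaned"`. Subjects with missing
values are dropped whole, with a message reporting how many remain. When a
censoring event is recorded on the same day as the last event, the last
episode looks fully observed (`d1 = d2 = 1`) and validation suggests adding
a small quantity to the censoring time.

The package follows the weighting that corrects the first problem
throughout: the *effective episode count* $m_i^* = m_i - 1$ for $m_i \ge 2$
(and $1$ for $m_i = 1$) divides each subject's contributions, so every
subject carries equal weight regardless of how many episodes fit into
follow-up.

## Nonparametric estimation

With $Z_{ij} = X_{ij} + Y_{ij}$, the joint CDF
$F_{X^0,Y^0}(x,y)$ is estimated by a weighted product-limit construction
over the distinct uncensored total gaps $t^*_k$:
$$\hat F(x,y) = \sum_{t^*_k \le x+y}\ \prod_{l<k}
  \Bigl\{1 - \tfrac{\hat H_a(t^*_l, \infty)}{\hat R_a(t^*_l)}\Bigr\}\,
  \frac{\hat H_a(t^*_k, (x,y))}{\hat R_a(t^*_k)},$$
with jump and at-risk functions
$$\hat H_a(z, (x,y)) = \tfrac1n \sum_i \tfrac{a_i I(m_i \ge 2)}{m^*_i}
  \sum_{j\le m^*_i} I(Z_{ij}=z, X_{ij}\le x, Y_{ij}\le y), \qquad
  \hat R_a(z) = \tfrac1n \sum_i \tfrac{a_i}{m^*_i}
  \sum_{j\le m^*_i} I(Z_{ij}\ge z).$$
The weight is $a_i = 1$ (`ai = 1`, default) or $a_i = C_i$ (`ai = 2`); the
observed table does not carry $C_i$, so it is reconstructed as the subject's
total observed follow-up, which is exact because the last Type II gap is
censored at $C^*$ by construction. The marginal survival of Type I gaps uses
the same structure on $X$ alone. Ties among jump times are processed once
with aggregated mass, and the left limit $S(s-)$ inside the integral is
realized exactly as the strictly-earlier-jumps product above.

Three numerical decisions deserve a note:

* **Support bound.** Estimates are only defined for $x + y \le \tau_c$, the
  maximal support of the censoring law. We estimate $\tau_c$ by the largest
  observed *subject-level* follow-up $\max_i C_i$ (not the largest single
  episode: a single gap can never exceed a follow-up window, and the
  censoring support is a property of follow-up). Grid cells beyond the bound
  are returned as `NA`, never extrapolated.
* **Conditional CDF.** For $\Pr(Y^0 \le y \mid v_1 \le X^0 \le v_2)$ we use
  the probabilistically coherent difference ratio
  $[\hat F(v_2,y) - \hat F(v_1,y)]\,/\,[\hat S_X(v_1) - \hat S_X(v_2)]$,
  which at population level equals the target conditional probability;
  $v_1 = 0$ recovers the single-bound form $\hat F(x,y)/(1-\hat S_X(x))$.
  Because numerator and denominator are estimated separately the raw ratio
  can leave $[0,1]$ in finite samples; reported values are clipped and the
  raw ones kept in a `raw` column.
* **Uncertainty.** Standard errors and pointwise intervals come from a
  subject-level bootstrap (default 200 replicates, seedable), with
  normal-quantile intervals clipped to $[0,1]$. The closed-form influence
  functions of the limiting Gaussian process are not implemented; the
  bootstrap applies uniformly to joint, marginal and conditional estimates.
  A bootstrap replicate that happens to contain no uncensored episode is
  redrawn up to ten times, then skipped with a warning.

Default evaluation grids, when the user gives none, are the deciles of the
observed uncensored gaps of each type.

## The accelerated failure time model

Covariate effects on both gap types are modelled log-linearly,
$$\log X^0_{ij} = \gamma_{i1} + A_i'\beta_1 + \varepsilon_{ij1}, \qquad
  \log Y^0_{ij} = \gamma_{i2} + A_i'\beta_2 + \varepsilon_{ij2},$$
with subject frailties $\gamma_i$ carrying within-subject correlation and
errors from unspecified mean-zero laws. Only baseline covariates are
admissible; a covariate that varies across a subject's episodes raises
`"Error: Time-varying covariates not allowed"`.

### The smooth U-statistic method (default)

For subject pairs $(i, i')$ with contrasts $A_{ii'} = A_{i'} - A_i$, the
estimating functions compare each observed gap with its pairwise-transformed
counterpart through the bounded log-scale kernel
$O_L(s,t) = \log[\min\{\max(t,s),L\}] - \log L$, inverse-weighted by a
Kaplan–Meier estimate $\hat G$ of the censoring survival built from
first-episode data with censoring as the event. $D_1^*(b_1) = 0$ is solved
first, then $D_2^*$ with $b_1$ fixed; the functions are smooth and
componentwise monotone, so a damped Newton iteration with a
central-difference Jacobian (step $10^{-5}\max(1,|b_k|)$, residual tolerance
$10^{-8}$) converges in a handful of steps to the unique root.

The evaluation bound is scale-matched: $L_1$ is the largest *uncensored*
first-episode Type I gap and $L_2$ the largest uncensored first-episode
total gap. This guarantees $\hat G(t \wedge L) > 0$, because the censoring
Kaplan–Meier can only reach zero beyond its largest observation and only
when that observation is a censoring event — in which case the largest
uncensored time sits strictly below it. Both bounds are overridable; exact
ties that still produce a zero weight are floored at the smallest positive
estimate with a warning.

The covariance is a hybrid sandwich
$\hat\Sigma^{-1}\hat\Omega(\hat\Sigma^{-1})'$: $\hat\Sigma$ is the numerical
Jacobian of the stacked estimating functions at the fit (block
lower-triangular, since $D_1^*$ does not involve $b_2$), and $\hat\Omega$ is
the subject-level bootstrap covariance of the stacked functions at the fit
(default 200 replicates), with $\hat G_1, \hat G_2$ recomputed on each
replicate while $L$ stays fixed as part of the functional's definition. The
closed-form middle matrix of the asymptotic theory is not reproduced here;
the bootstrap stands in for it, and a Wald construction (two-sided normal
p-values) is used for intervals throughout.

### The rank-based method

The older rank-based approach transforms gaps to the baseline scale,
$\tilde X^0_{ij}(b) = X_{ij}e^{-A_i'b_1}$ and
$\tilde Z^0_{ij}(b) = X_{ij}e^{-A_i'b_1} + Y_{ij}e^{-A_i'b_2}$, truncating
at the transformed residual follow-up
$C_i e^{-A_i'b_1} - \sum_{l<j}\tilde Z_{il}(b)$, and centers each
covariate at its weighted risk-set mean. Two implementation points matter:

* **Completeness on the transformed scale.** The outer sums run over
  episodes whose transformed gap escaped the truncation bound; truncated
  transformed times stay in the risk sets, exactly as censored observations
  enter Kaplan–Meier risk sets. The bound depends on the covariates, so
  omitting this restriction leaves the functions off-center at the true
  coefficients (empirically by more than one unit of $b$ at $n = 400$ under
  the default scenario).
* **Step-function solving.** $U_1, U_2$ are step functions of $b$, so
  derivative-based solvers do not apply and an exact root rarely exists. We
  minimize $\|U\|^2$ by a Nelder–Mead simplex from five deterministic starts
  ($0$, $\pm 0.5$ patterns), iterating the two blocks twice because $U_1$
  depends on $b_2$ through the truncation bound. Convergence is declared
  when the attained $\|U\|_\infty$ falls below `tol` (default 1): the
  $\sqrt n$-scaled functions have unit-order sampling scale at the root, so
  any attained crossing passes, while degenerate systems — for example a
  covariate without variation, which admits no isolated root — sit far above
  and raise `"Error: Max Iterations reached. Did not converge."`.

Its covariance comes from perturbed-equation resampling: replicate $r$
solves $U(b) = Z_r$ with $Z_r \sim N(0, \hat\Omega)$, where $\hat\Omega$
estimates the sampling covariance of $U$ at the fit from per-subject
contributions. Drawing the perturbation from the estimating function's own
scale matters: unit-variance draws routinely exceed the attainable range of
the step functions and would be reported as replicate nonconvergence. The
replicate solutions' empirical covariance is the variance estimate; if more
than 20% of replicates fail their tolerance the function stops and advises
the smooth method. Note an asymmetry of this method: its Type II transformed
time mixes two exponential scales, so (unlike the smooth method, whose
pairwise contrasts make it exactly location-invariant) shifting a covariate
by a constant perturbs the Type II risk-set order in finite samples; scale
equivariance, $U(b/k)$ on a $k$-scaled covariate equalling $k\,U(b)$, is
exact for both.

The rank-based path costs minutes where the smooth path costs seconds, and
its intervals are wider; it is provided for comparison, with the smooth
method as the recommended default.

## The simulator

`sim_bivgap()` generates data from the model above: `a1 ~ Bernoulli(0.5)`,
`a2 ~ Uniform(0,1)`, frailties bivariate normal, log-scale errors normal,
censoring `C ~ Uniform(0, tau_c)`; episodes are generated until the
cumulative total gap first exceeds $C_i$ and the straddling pair is kept, so
the truncation identity above holds by construction. Observed data are then
assembled exactly per the censoring mechanics: a subject censored at the
very start of an episode yields a degenerate `(0, 0, 0, 0)` row, which
validation accepts because zero gaps are only legal with zero indicators.
Draws occur in a fixed order (covariates, frailties, censoring times, then
per-subject gap errors), so one seed pins down the whole dataset across
platforms.

The scenario defaults labelled `set = "1.1"` — frailty mean $1.1$, variance
$0.25$, correlation $0.5$, error SD $0.5$ — are the package's calibration of
the canonical simulation design for these methods: with $n = 150$,
$\beta_1 = (0.5, 0.5)$, $\beta_2 = (0, -0.5)$ and $\tau_c = 63$ they give an
average first-pair censoring rate of about 15%, the documented rate for that
design ($E[Z] \approx 9.7$ against $E[C] = 31.5$). Every field is
overridable.

What the generator does *not* emulate: real registry features such as
discrete (day-resolution) times and the exact-tie pathologies they cause,
covariate-dependent censoring, heavy-tailed or skewed frailty laws, and
time-varying covariates. Passing tests on simulated data therefore
demonstrate internal correctness and calibration under the stated model, not
robustness to those departures.

## What the test suite computes

Every estimator is checked against an independently written brute-force
implementation (naive loops straight from the displayed formulas) to
$10^{-12}$ on small random tables, and against hand-computed values on a
three-subject toy table. Stochastic checks use fixed seeds and these problem
sizes, chosen to estimate each quantity to well inside its tolerance: 500
simulated datasets for the censoring-rate calibration; 100 replicates of the
default scenario for coefficient recovery (bias within 3 Monte-Carlo SEs)
and 95% Wald coverage (required inside [0.90, 0.99]); 16 null-scenario
replicates for the rank-based method's null recovery; and 10 replicates of
$n = 500$ for convergence of the marginal survival estimator to a known
lognormal margin (max error below 0.05).

## Limitations

The Type II marginal is not estimable (by design of the problem, not the
package); closed-form asymptotic variances are replaced by resampling; the
frailty law and the latent frailties themselves are not estimated; and
same-day events must be broken by the user (the validation error says how).
Wide-format and calendar-time encodings are out of scope.
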