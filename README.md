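# bivgap

Nonparametric and semiparametric analysis of **bivariate alternating
recurrent event data**: processes in which each subject cycles repeatedly
through two states — care periods and break periods, hospitalization and
community time — until follow-up ends. Episode *j* of subject *i* is a pair
of gap times (X<sub>ij</sub>, Y<sub>ij</sub>); the last Type II gap is
always censored, and the number of episodes a subject contributes is itself
informative (fast cyclers fit more episodes into the same follow-up). The
package is written for biostatisticians analysing such registries and for
methodologists simulating them.

## What it computes

* **Validated data objects** (`episode_table()`, `read_episodes()`): long
  format, one row per episode, with the structural rules enforced
  (`"Error: Data not cleaned"` on violation) and whole-subject deletion of
  missing values.
* **Nonparametric estimation** (`bivgap_np()`): the joint CDF of the two
  gap types by a weighted product-limit estimator over uncensored total
  gaps,

  F̂(x, y) = Σ<sub>t\*≤x+y</sub> Π<sub>l&lt;k</sub>
  {1 − Ĥ<sub>a</sub>(t\*<sub>l</sub>, ∞)/R̂<sub>a</sub>(t\*<sub>l</sub>)} ·
  Ĥ<sub>a</sub>(t\*<sub>k</sub>, (x, y))/R̂<sub>a</sub>(t\*<sub>k</sub>),

  with all sums weighted by the effective episode count m\* = m − 1 to
  offset informative episode numbers; the marginal survival of Type I gaps;
  and the conditional CDF of Type II given an interval of Type I gaps (the
  Type II marginal itself is not identifiable under induced dependent
  censoring). Standard errors by subject-level bootstrap.
* **AFT regression for both gap types** (`bivgap_reg()`): log-linear
  covariate effects log X⁰ = γ₁ + A'β₁ + ε₁, log Y⁰ = γ₂ + A'β₂ + ε₂ with
  subject frailties, fitted by a smooth U-statistic method (default,
  sandwich covariance) or the classical rank-based method (simplex search,
  perturbed-equation resampling covariance). `summary()`, `coef()`,
  `vcov()`, `confint()` behave as in `survival`-style fits.
* **A scenario simulator** (`sim_bivgap()`) implementing the exact
  censoring/truncation mechanics, calibrated so the default design censors
  about 15% of first pairs.
* **Plots** (`plot_events()`, `plot_joint()`, `plot_marginal()`,
  `plot_conditional()`) and a thin command-line wrapper
  (`inst/cli/bivgap.R`) with subcommands `sim | validate | np | reg | plot`.

## Worked example

```r
library(bivgap)

tab <- sim_bivgap(sim_scenario(seed = 7))   # n = 150, default scenario
head(tab$data)
#>   id episode      xij      yij d1 d2 a1         a2       zij        ci
#> 1  1       1 5.002286 1.033519  1  0  1 0.09244647  6.035805  6.035805
#> 2 10       1 9.636895 3.925870  1  1  0 0.81109953 13.562764 61.988595
#> 3 10       2 5.743600 4.460744  1  1  0 0.81109953 10.204344 61.988595
```

Subject 1 was censored during its first break period (`d2 = 0` ends every
trajectory); subject 10 contributes many complete episodes.

```r
np <- bivgap_np(tab, u1 = c(5, 10, 20), u2 = c(5, 10, 20),
                n_boot = 100, seed = 1)
np$joint_cdf
#>    x  y       cdf         se    ci_low   ci_high
#> 1  5  5 0.4209420 0.03359700 0.3550931 0.4867909
#> 2 10  5 0.7187812 0.03455107 0.6510623 0.7865000
#> 3 20  5 0.8728719 0.02233729 0.8290916 0.9166522
#> ...
np$tau_c_hat
#> [1] 62.37983
```

The estimated probability that a care period lasts at most 10 and the
following break at most 5 time units is 0.72 (bootstrap 95% CI 0.65–0.79);
cells with x + y beyond the estimated support (62.4 here) would be `NA`.

```r
fit <- bivgap_reg(tab, n_resample = 200, seed = 1)
summary(fit)
#> AFT model for bivariate alternating gap times (method: lee)
#> n = 150 subjects; residual norm 1.21e-12; level 0.95
#>
#>        estimate     se       z p-value  ci_low ci_high exp(estimate)
#> xij a1   0.4086 0.1285  3.1805  0.0015  0.1568  0.6604        1.5047
#> xij a2   1.0294 0.2482  4.1476  0.0000  0.5429  1.5158        2.7993
#> yij a1  -0.4212 0.2634 -1.5988  0.1099 -0.9374  0.0951        0.6563
#> yij a2  -1.0737 0.4960 -2.1649  0.0304 -2.0457 -0.1016        0.3418
```

Coefficients are on the log gap-time scale: here a1 = 1 multiplies Type I
gap lengths by exp(0.41) ≈ 1.50 (data were generated with a true effect of
0.5), and `confint(fit, parm = "xij a1")` gives the Wald interval for that
single effect.

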