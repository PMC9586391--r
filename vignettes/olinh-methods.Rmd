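---
title: "Methods: the OLINH lifetime distribution and its estimators"
author: "olinh package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the OLINH lifetime distribution and its estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olinh)
```

## The model

The inverted Nadarajah-Haghighi (INH) distribution is the law of $1/Y$
when $Y$ is Nadarajah-Haghighi.  Its CDF on $x > 0$ is

$$G(x) = \exp\{1 - (1 + \delta/x)^\theta\}, \qquad \delta, \theta > 0,$$

a right-skewed family with decreasing or upside-down-bathtub hazard.  The
odd Lomax construction passes any baseline CDF $G$ through the Lomax CDF
evaluated at the odds $G/(1-G)$:

$$F(x) = 1 - \beta^\alpha\Big[\beta + \tfrac{G(x)}{1-G(x)}\Big]^{-\alpha},
  \qquad \alpha, \beta > 0.$$

With the INH baseline this yields the four-parameter OLINH distribution.
Two structural facts drive everything else in the package:

* **Reduction.** At $\alpha = \beta = 1$ the transform is the identity,
  so OLINH nests INH exactly.  This is used both as a correctness test
  and as the nested comparator in model selection.
* **Tail.** The baseline odds grow linearly, $G/(1-G) \sim x/(\theta\delta)$,
  so the OLINH survival function is asymptotically
  $\beta^\alpha(\theta\delta)^\alpha x^{-\alpha}$: a power-law right tail
  of index $\alpha$.  Moments of order $r$ exist iff $r < \alpha$, and
  the moment generating function diverges for every $t > 0$ (it is
  provided on $t \le 0$ only).

All distribution functions are evaluated through shared stable
intermediates.  With $T = (1+\delta/x)^\theta$ computed as
$\exp\{\theta\,\mathrm{log1p}(\delta/x)\}$, the survival of the baseline
is `-expm1(1 - T)` (never $1 - e^{1-T}$), the OLINH survival is computed
directly from the odd Lomax survival form with a log-sum-exp for
$\log(\beta + \mathrm{odds})$, and the quantile function inverts the CDF
analytically through `expm1`/`log1p` forms that stay exact in both tails.
The quantile printed in some accounts of this family carries a
typographical slip in the inner term; the package implements the direct
algebraic inversion of $F$ and enforces $F(Q(q)) = q$ to $10^{-9}$ across
$q \in [0.001, 0.999]$ in its test suite, which settles the form.

Sampling is by inverse transform: exact, rejection-free, and reproducible
from an explicit seed, which every randomized function accepts.

## Distributional summaries

Quadrature against the exact density is the authoritative computation for
moments, incomplete moments, the MGF on $t \le 0$, and Rényi entropy.
Integrals are split at the distribution median, and the region below the
median is mapped through $x = \delta/u$ so the quadrature grid resolves
the boundary layer of the inverted baseline near zero.

The classical series expansion of odd Lomax-G densities in powers of the
baseline CDF is implemented as a *truncated cross-check only*
(`dolinh_series`, `polinh_series`).  Two notes on it:

* Direct expansion of $[\beta + G/(1-G)]^{-\alpha-1}$ gives the
  coefficient $\Delta_{k,j} \propto \beta^{-(k+1)}$, with leading term
  $f \to (\alpha/\beta)\,g$ as $G \to 0$ — the form the package uses,
  verified by convergence of the partial sums to the closed-form density.
  (Some printed accounts carry $\beta^{k+1}$, which fails that check.)
* The further term-by-term integrated series for moments and entropy do
  not terminate in computable form (they contain a divergent product over
  the expansion index); they are treated as formal and never evaluated.
  Quadrature replaces them.

Skewness and kurtosis are reported as the quantile-based Bowley and Moors
measures: with a power tail of index $\alpha$, moment-based shape
measures would not exist for $\alpha \le 3$ resp. $\alpha \le 4$, while
the octile-based measures are finite for every parameter value.

## Maximum likelihood, and the shape of this likelihood

The log-likelihood is maximized with $\alpha$ profiled out: its score
equation has the closed-form root
$\hat\alpha = n / \sum_i \log\{[\beta + G_i/(1-G_i)]/\beta\}$, always
positive and finite, so the numerical search runs over
$(\log\beta, \log\delta, \log\theta)$ only.  `olinh_mle` multi-starts
this 3-D search from eight deterministic points (an INH maximum
likelihood fit and a quantile-matched INH fit, crossed with
$\beta_0 \in \{0.5, 2\}$ and a large-$\delta$ probe), polishes the winner
jointly in all four parameters with the analytic score, and takes
standard errors from the inverse observed information (central
differences, relative step $10^{-4}$), with a spectral pseudo-inverse and
a flag when the information matrix is not positive definite.  Wald
intervals are reported on the parameter scale, floored at zero.

Users of this family should know that its likelihood is *ridge-shaped*
in $(\delta, \theta)$, for a structural reason: the family contains
boundary sub-models.  As $\delta \to 0$, $\theta \to \infty$ with
$\delta\theta \to \lambda$, the baseline converges to
$\exp\{1 - e^{\lambda/x}\}$ (an inverted Gompertz-type law), and the
reverse corner behaves symmetrically.  Consequences, all observable with
this package:

* On real data the maximized likelihood can sit at very large $\delta$
  with small $\theta$ (the packaged vaccination data do exactly this,
  $\hat\delta \approx 717$, $\hat\theta \approx 0.21$), with an
  information matrix that is nearly singular along the ridge — the
  reported standard errors for $\delta$ are then very large, and honest.
* In simulations at moderate $n$, a non-negligible fraction of samples
  have their likelihood supremum *on* the boundary, so the unrestricted
  MLE of $(\beta, \delta, \theta)$ escapes while the fitted distribution
  function barely moves.  The estimator is consistent as a distribution
  estimate long before the ridge coordinate is pinned down; the test
  suite checks exactly that (sup-distance of the fitted CDF) alongside
  recovery of the well-identified tail index $\alpha$.

## Bayesian estimation

Independent gamma priors on all four parameters lead to an exact gamma
full conditional for $\alpha$ — derived from the joint posterior, its
rate is $\nu_1 + \sum_i \log\{[\beta + G_i/(1-G_i)]/\beta\}$, where
folding the $\beta^{n\alpha}$ likelihood factor into the sum keeps the
rate strictly positive — and non-standard conditionals for $\beta$,
$\delta$, $\theta$, which are updated by Gaussian random walks on the log
scale with the Jacobian-corrected acceptance ratio.  The scan order is
systematic: exact $\alpha$ draw, then the three MH updates.

Chain defaults are 5000 iterations with 1000 burn-in, thinning 1, HPD
level 0.95.  Proposal scales adapt only during burn-in (multiplied by
0.7 or 1.4 when the windowed acceptance leaves $[0.2, 0.5]$) and are
frozen afterwards, so the retained chain is a valid fixed-kernel MCMC.
Point estimates are retained-draw means (the Bayes rule under squared
error loss); intervals are shortest-interval HPDs, never longer than the
equal-tailed interval.

Prior hyperparameters for recovery experiments default to
$\mu_p = \nu_p = 0.1$ (prior mean 1, variance 10, weakly informative);
no published choice exists for this family, so this is the package's own
default and recovery tests use it.  On the ridge, the prior's pull
towards moderate values regularizes the posterior noticeably — the
Bayesian point estimates are much better behaved at small $n$ than the
unrestricted MLE, which is the practical argument for them here.

## Goodness of fit

`gof_report` computes KS (with the asymptotic Kolmogorov p-value — at
$n = 46$ the asymptotic law is adequate), Cramér-von Mises and
Anderson-Darling from the ordered probability integral transforms, and
four information criteria.  CAIC is the small-sample corrected AIC,
$AIC + 2k(k+1)/(n-k-1)$: the printed comparison tables this package
reproduces fix that convention unambiguously through their own
arithmetic.  PIT values that reach 0 or 1 exactly are clipped at
$10^{-10}$ with a warning before the AD logarithms.  `compare_models`
ranks by AIC, then BIC, then name.

One honest caveat on the packaged comparison: for the vaccination data
the correctly-maximized INH likelihood is $-143.548$ (AIC $291.10$),
which is *lower* AIC than OLINH's $292.18$ — the two extra parameters
buy about 1.5 log-likelihood units, less than the AIC penalty.  OLINH
still dominates on every distance statistic (KS $0.0856$ vs $0.0890$,
AD $0.318$ vs $0.366$).  Fit both and look at both, which is what the
`gof` interface does.

## The Monte-Carlo harness

`olinh_sim_cell` repeats: draw $n$ inverse-transform samples at a known
truth (per-replicate seeds derived from the master seed by a
counter-based scheme, so cells are reproducible and order-independent),
estimate, and summarize bias, relative bias, MSE
($N^{-1}\sum_j(\hat\omega_j - \omega)^2$), mean interval length, and
coverage.  The MLE inside a cell is started at the truth — the standard
choice in recovery experiments — and left unconstrained; Wald coverage
for each parameter is computed over the replicates where that
parameter's inverse-information diagonal is a positive variance, with
the invalid count reported.  Given the boundary-escape behaviour
described above, the MSE of $\hat\beta$, $\hat\delta$, $\hat\theta$ at
$n \le 150$ is dominated by rare escaped replicates and can be
astronomically large; $\hat\alpha$'s metrics are stable and are the ones
the package's acceptance checks pin down (MSE $\approx 0.12$, coverage
$\approx 95\%$ at $n = 150$ with 1000 replicates).

Problem sizes used by the packaged checks: 1000 replicates per cell at
$n \in \{30, 80, 150\}$ for the MLE study; Bayesian recovery at
$n = 2000$ with the default 5000-iteration chain; distributional
Monte-Carlo cross-checks at $10^5$–$10^6$ draws.

## Known limitations

* Only the INH baseline is wired into the odd Lomax transform; `polg` is
  exposed, but there is no general plugin mechanism for other baselines.
* Complete samples only — no censoring support in either estimator.
* The likelihood ridge means point estimates of $(\beta, \delta, \theta)$
  from small samples should be read as a coordinate on a near-flat
  surface, not as separately-identified quantities; report the fitted
  distribution, the profile of $\alpha$, or Bayesian summaries instead.
* KS p-values use the asymptotic law; for very small $n$ an exact
  p-value would differ in the second decimal.
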