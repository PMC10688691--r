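---
title: "Stress-strength reliability for inverse Pareto lifetimes under progressive first-failure censoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-strength reliability for inverse Pareto lifetimes under progressive first-failure censoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssripd)
```

## The model

A system survives while its strength $X$ exceeds the stress $Y$ applied to
it; the stress-strength reliability is $\phi = P(Y < X)$. `ssripd` models
both variables as independent inverse Pareto (IPD) lifetimes,
$$F(x \mid \alpha) = \Big(\frac{x}{1+x}\Big)^{\alpha}, \qquad
  f(x \mid \alpha) = \frac{\alpha\, x^{\alpha-1}}{(1+x)^{\alpha+1}},
  \qquad x > 0,\ \alpha > 0,$$
a one-parameter heavy-tailed law with decreasing or upside-down-bathtub
hazard, suitable for e.g. material-strength and failure-time data. For
$X \sim \mathrm{IPD}(\alpha_1)$ and $Y \sim \mathrm{IPD}(\alpha_2)$ the
reliability has the closed form
$$\phi = \frac{\alpha_1}{\alpha_1 + \alpha_2},$$
so every estimator of $\phi$ in the package is an estimator of the two
shapes pushed through this map.

All IPD computations run in log space — $\alpha \log\{x/(1+x)\}$ is formed
before exponentiating, with `log1p`/`expm1` at both tails — because realistic
fits can put $\alpha$ near 20, where direct powering of $x/(1+x)$ loses
precision. $x = 0$ lies outside the support; the cdf limit 0 there is used
only implicitly as the lower spacing boundary.

## Progressive first-failure censoring

In a progressive first-failure censoring (PFFC) design, $n$ groups of $k$
items go on test. At the $i$-th observed first failure, $G_i$ surviving
whole groups are withdrawn (plus the group that failed); the experiment
stops at the $m$-th failure, so $n = m + \sum_i G_i$. The observed data are
the $m$ ordered first-failure times. Special cases: $k = 1$ gives ordinary
progressive type-II censoring; $k = 1$ with all $G_i = 0$ gives a complete
sample.

A PFFC sample is distributionally a progressive type-II censored sample
from the first-failure law $1 - (1 - F)^k$. `rpffc()` exploits this through
the exact uniform-spacings construction: independent uniforms are powered
by the reversed partial sums of the scheme, cumulated into the ordered
uniforms, and pushed through the inverse of $1 - (1-F)^k$. The construction
is $O(m)$, exact (no rejection or discretization error), and fully
reproducible under a seed. Ties have probability zero in generated data;
validation accepts non-decreasing times so that rounded real data with
ties remain admissible.

## Estimators

**Maximum likelihood.** The two-sample log-likelihood separates additively
in $(\alpha_1, \alpha_2)$, with per-sample censoring exponents
$k(G_i + 1) - 1$ on the survivor terms. Each shape therefore solves its own
scalar score equation, handled by `uniroot` on a sign-change bracket grown
geometrically around the complete-sample closed form
$\hat\alpha_0 = m / (-\sum_i \ln u_i)$, $u_i = x_i/(1+x_i)$ — always the
right order of magnitude, and exact when the censoring exponents vanish.
Convergence tolerance on $\alpha$ is $10^{-12}$ (the problem is univariate
and cheap, so there is no reason to be lax).

**Delta-method interval.** Because the cross-partial of the log-likelihood
is identically zero, the observed Fisher information is diagonal, and
$\widehat{\mathrm{Var}}(\hat\phi) = q' I^{-1}(\hat\psi)\, q$ with
$q = \big(\alpha_2, -\alpha_1\big)'/(\alpha_1+\alpha_2)^2$. The asymptotic
interval is $\hat\phi \pm z_{\xi/2}\sqrt{\widehat{\mathrm{Var}}}$,
default level 0.95. Endpoints are reported raw; `clamp = TRUE` truncates
to $[0, 1]$ when an interval spills outside the unit interval for very
small $m$.

**Maximum product spacing.** The MPS criterion chooses $\alpha$ to
equalize the cdf increments at the ordered data (boundary values 0 and 1
taken exactly), plus the same survivor terms as the likelihood; the
survivor sum runs over the $m$ observed failures (the $m{+}1$-th spacing
has no removal attached to it). The objective is maximized directly by
`optimize` on $\log \alpha$, with the bracket expanded until the interior
maximum is certain — direct maximization was preferred over root-finding
the stationarity condition because for small $m$ the derivative can be
one-sided and a root-finder may land on the wrong feature; a maximizer
cannot. Tied observations make a spacing exactly zero and the log
objective $-\infty$; following the standard remedy in the product-spacing
literature, a spacing vanished by a tie is replaced by the density
$f(x_i; \alpha)$. The electrical-insulation data (values recorded to two
decimals, with repeats such as 0.07, 0.07 and 0.14, 0.14) are the
motivating case. This choice can shift tied-sample estimates relative to
other tie conventions; it is the documented behaviour, not a tuning knob.

**Bayes.** Independent $\mathrm{Gamma}(r_i, s_i)$ priors on the shapes
give conditionally independent marginal posteriors, each a gamma kernel
times the censoring survivor product — exactly gamma when the censoring
exponents vanish, which is the conjugate case the test suite uses to
validate the sampler end to end. Sampling is component-wise random-walk
Metropolis-Hastings with normal proposals; non-positive proposals are
rejected outright so the support is respected. Defaults: initialization at
the MLEs, proposal standard deviations equal to the delta-method standard
errors $\sqrt{I^{-1}}$ (falling back to $0.1 \hat\alpha$ if the
information is degenerate) — this targets acceptance rates in the 0.2–0.5
band without manual tuning — $M = 10000$ draws, $M_0 = 2000$ burn-in, and
near-flat analysis priors $r_i = s_i = 10^{-4}$ when no prior knowledge is
supplied. The point estimate under squared-error loss is the post-burn-in
mean of the $\phi$ chain. The HPD credible interval scans every window of
$\lfloor (1-\xi) M \rfloor$ consecutive order statistics and returns the
shortest, ties broken at the smallest start, endpoints always observed
draws. The proposal variance is the one genuinely free knob of the
sampler; different choices perturb the Monte Carlo error, not the target.

## The Monte Carlo study harness

`mc_study()` replicates the whole pipeline — generate paired PFFC samples
at true shapes, estimate, summarize — reporting the average estimate (AV),
mean squared error (MSE) and average interval length (AL) per estimator.
Replicates where a solver fails are dropped and counted rather than
aborting the run, the usual practice for long simulation studies. The
default Bayes-arm prior sets the prior means equal to the true shapes
(rates 2 and 4), the standard informative design for such studies.

The generator's default study conditions are the classical ones for this
design family: true shapes $(2, 0.5)$ or $(1.2, 0.8)$ (so $\phi = 0.80$ or
$0.60$), schemes removing five of $n = 25$ groups (front-, mid- or
back-loaded), group sizes $k = 2$ to $4$, and 1000 replications. A
full-scale Bayes arm (1000 replications of 10000-draw chains) is a long
run by design; the harness accepts reduced presets and records the `R`,
`M`, `M0` actually used in its output. The test suite exercises the Bayes
arm at $R = 500$ replications with 2000-draw chains and the classical arms
at $R = 1000$ — sizes chosen so the whole suite stays comfortably
desk-scale while keeping Monte Carlo error well below the effects being
asserted.

What the generator emulates — and what it does not: it produces exact
draws from the stated design, i.e. data whose only departure from the
model is sampling noise. Real strength data bring rounding (hence ties),
possible model misspecification, and group formation that may not be
random. Passing simulation tests therefore validate the estimators under
the model, not the model's fit to any particular data set; the KS
goodness-of-fit step (`ks_test_ipd`, asymptotic p-values, parameters
plugged in at the MLE — a knowingly anti-conservative simplification) is
the tool provided for the latter question.

## Embedded data and reproduction of the published analyses

Two classical paired data sets ship with the package (`pffc_dataset()`):
jute-fibre breaking strengths at 15 mm and 20 mm gauge lengths
($n = 15$ groups of $k = 2$), and failure times of two electrical
insulation types ($n = 10$ groups of $k = 3$), each with four published
PFFC sub-samples and their censoring schemes, stored exactly as printed in
the source analyses — including their internal inconsistencies, which are
preserved rather than corrected.

Those inconsistencies matter for one family of checks. The complete-sample
ML fits and KS distances reproduce the published values to four decimals.
The published scheme-wise MPS/ML/ACI/Bayes table values, however, are not
recoverable from the published sub-samples: the sub-samples disagree with
the published first-failure lists they are nominally drawn from (the
zero-removal sub-samples, which must equal those lists, contain values
absent from them), and on the printed data this package's MPS, ML and
exact posterior-mean computations agree closely with one another while the
published row values scatter far more widely than any coherent computation
on shared data could. The package therefore reports what the stated
formulas give on the stated data; the corresponding reproduction tests
document the discrepancy rather than absorb it. The simulation study,
which exercises the identical code paths end to end, does reproduce the
published Monte Carlo averages within Monte Carlo error, and is the
validation the package stands on.

## Numerical choices, in one place

* Log-space cdf/quantile evaluation throughout; `log1p`/`expm1` at tails.
* ML: bracketed `uniroot`, tolerance $10^{-12}$, bracket grown from the
  closed-form start; MPS: `optimize` on $\log\alpha$, tolerance $10^{-10}$,
  starting bracket $(10^{-3}, 10^{3})$ expanded geometrically, error if the
  objective keeps rising at the boundary (degenerate one-point samples can
  push the maximizer to infinity).
* Spacing boundaries $F(x_0) = 0$, $F(x_{m+1}) = 1$ exact; tie spacings
  replaced by the density.
* HPD window length uses `floor`; ties at the smallest start index.
* ACI endpoints unclamped by default.
* Failed Monte Carlo replicates dropped and counted.

## Limitations

Only the one-parameter IPD family is supported; hazard-shape analytics are
out of scope. Interval estimation for the MPS estimator is not provided
(point estimation only, as intervals here are built from the ML and
posterior routes). The KS p-values do not correct for estimated
parameters. MCMC diagnostics are limited to acceptance rates, trace/density
plots and CSV export — formal convergence statistics are left to dedicated
MCMC tooling.
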