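---
title: "Partial metric invariance and the testing of latent moderation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial metric invariance and the testing of latent moderation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invarimod)
```

## The problem

A moderation effect with a categorical moderator is, in the multiple-group
SEM tradition, the difference of a structural slope between groups:
$\Delta\gamma = \gamma_1 - \gamma_2$. Testing it presumes that the latent
predictor and outcome are *measured the same way* in both groups — at
minimum, metric invariance (equal factor loadings). This package provides a
fully scripted Monte Carlo pipeline for asking what happens to the estimate
$\widehat{\Delta\gamma}$ and its Wald test when metric invariance fails in
the population but the analyst assumes it anyway, and whether freeing
exactly the non-invariant loadings (partial metric invariance) repairs the
damage. Two designs are covered: a single-level two-factor model, and a
two-level model in which the moderator is a group variable at the cluster
level and the slope of interest is within-cluster ("cross-level"
moderation).

## The single-level model

Per group $g \in \{1, 2\}$, six indicators each for the latent predictor
$F_X$ and the latent outcome $F_Y$:

$$
\mathbf{X}_g = \boldsymbol{\lambda}_{Xg} F_{Xg} + \boldsymbol{\delta}_g,
\qquad
\mathbf{Y}_g = \boldsymbol{\lambda}_{Yg} F_{Yg} + \boldsymbol{\varepsilon}_g,
\qquad
F_{Yg} = \gamma_g F_{Xg} + \zeta_g .
$$

The population sets all loadings to 0.7 in group 1. Non-invariance lowers
the **last** $p_{ni} \in \{0, 2, 4\}$ loadings of one factor (the
"location", predictor or outcome side) to 0.3 in group 2; putting the
non-invariance at the end keeps the marker (indicator 1) invariant, which
the identification requires. Factor variances are 1.0 in group 1 and 1.3 in
group 2 for both factors; the structural disturbance is derived as
$\psi_g = \phi_{Yg} - \gamma_g^2 \phi_{Xg}$ so the outcome factor keeps its
stated total variance.

Unique variances hold **every** indicator's total variance at the group's
factor variance: 0.51 in group 1, and in group 2 $1.3(1 - \lambda^2/1)$,
i.e. 0.663 for invariant indicators and 1.183 for non-invariant ones. The
alternative reading — 0.663 for all group-2 indicators, which would give
non-invariant indicators a total variance of 0.78 — was implemented and
rejected: it produces systematically larger contrast distortions than the
variance-preserving convention, and only the latter is consistent with the
study's stated design logic that indicators carry the group factor variance.
This is the single most consequential population choice in the package;
everything downstream (pseudo-true contrast values, rejection rates,
standardized biases of the invariance-assuming fits) moves with it.

The design grid crosses $p_{ni}$, four slope pairs
$\{0.1,0.1\}, \{0.5,0.5\}, \{0.5,0.33\}, \{0.33,0.5\}$ (equal pairs probe
Type I error, unequal pairs probe power), the location, and per-group sizes
$N \in \{200, 500\}$ — 40 cells, since location is undefined at
$p_{ni} = 0$:

```{r}
length(designGrid(1))
head(conditionTable(1))
```

## The two-level model

Per group, a six-indicator latent predictor measured at both levels with the
*same* loadings $\boldsymbol{\lambda}_g$ (metric invariance across clusters),
an observed within-level outcome, and no between-level structural path:

$$
\text{within:}\quad
Y_{ijg} = Y_{(b)jg} + \gamma_{10g} F_{X(w)ijg} + r_{ijg},\qquad
\mathbf{X}_{ijg} = \mathbf{X}_{(b)jg}
  + \boldsymbol{\lambda}_g F_{X(w)ijg} + \boldsymbol{\delta}_{(w)ijg},
$$
$$
\text{between:}\quad
Y_{(b)jg} = \gamma_{00g} + \zeta_{jg},\qquad
\mathbf{X}_{(b)jg} = \boldsymbol{\alpha}_g
  + \boldsymbol{\lambda}_g F_{X(b)jg} .
$$

Between-level indicator residuals are exactly zero. Group 1 loadings are
$(0.7, 0.3, 0.5, 0.6, 0.7, 0.7)$; the printed design states only that the
two potentially non-invariant loadings are 0.7 and that the other four are
0.7, 0.3, 0.5 and 0.6, so the assignment to positions is a package choice:
the marker (position 1) takes 0.7 — it must be invariant and is fixed to
0.7 in the analysis — and the non-invariant pair sits last, dropping to 0.3
in group 2 when $p_{ni} = 2$. Within-level factor and outcome variances are
1, level-1 unique variances 0.5. The intraclass correlation
$\rho \in \{0.10, 0.35\}$ of both the latent predictor and the outcome maps
to the between variances as $\rho/(1-\rho)$ (the standard definition with
within variance 1; the design states only that the between variances are
"functions of the ICC"). The grid crosses $p_{ni} \in \{0,2\}$, slope pairs
$\{0.3,0.3\}$ / $\{0.3,0.2\}$, ICC, clusters per group $m \in \{30, 100\}$
and cluster size $c \in \{5, 20\}$ — 32 cells, all balanced.

## Generation

Latent scores and residuals are drawn directly from the generative equations
(never via a Cholesky factor of the implied covariance), so the generator
and the implied-moment algebra are independent derivations that the test
suite checks against each other at large $N$. Replication $r$ of grid cell
$k$ seeds the stream with $(\text{base} + 10^6 k + r) \bmod (2^{31}-1)$, and
group 2 offsets its substream, so results are reproducible cell by cell,
group 1's data never depend on group 2's parameters, and adding cells to a
run perturbs nothing. All means are zero.

What the generator deliberately does **not** emulate: non-normal or
categorical indicators, unbalanced clusters, missing data, intercept
(scalar) non-invariance, and random slopes. Passing tests therefore speak to
the behaviour of the estimators under exactly normal, balanced, zero-mean
data — the conditions of the study design — and not to robustness beyond
them.

## Estimation

Both analysis models are fitted by normal-theory maximum likelihood with
parameter sharing implementing the equality constraints. The
full-metric-invariance scheme ("MI") constrains all loadings cross-group
equal; the partial scheme ("pMI") frees exactly the truly non-invariant ones
in each group. Identification fixes the marker loadings to 0.7 in both
groups and leaves factor variances, unique variances and (single-level)
disturbances free per group. Latent means are fixed at zero and observed
intercepts are saturated per group, so the mean structure separates and the
fit reduces to the covariance structure.

Single level, the discrepancy
$F = \sum_g \tfrac{n_g}{n}\bigl[\ln|\Sigma_g(\theta)| +
\mathrm{tr}(S_g \Sigma_g(\theta)^{-1}) - \ln|S_g| - p\bigr]$
is minimized with an analytic gradient. Two level, the exact profiled
likelihood for balanced data is written on the pooled within-cluster
covariance $S_{PW}$ (divisor $n - m$) and the scaled between covariance
$S_B$ (divisor $m - 1$):
$-2\ell = (n-m)\bigl[\ln|\Sigma_W| + \mathrm{tr}(\Sigma_W^{-1}S_{PW})\bigr]
 + m\ln|\Sigma^*| + (m-1)\,\mathrm{tr}(\Sigma^{*-1}S_B)$
with $\Sigma^* = \Sigma_W + c\,\Sigma_B$; the test suite verifies this
equals a direct per-cluster evaluation of the $(cp)$-dimensional normal
density to $10^{-6}$. Because the maximum-likelihood weights are $m$ and
$m-1$, a fit to *expected* moments sits a factor $(m-1)/m$ off the supplied
between matrix; `weighting = "moment"` equalizes the weights so that
fixed-point recovery from population-implied moments is exact, and is the
mode used for population-level (pseudo-true) fits.

Numerical choices: variances are optimized on the log scale, which keeps
every implied matrix positive definite by construction and turns Heywood
cases into floored boundary solutions (flagged, and counted by the harness
rather than discarded); starting values are generic (loadings 0.5, variances
1, slopes 0), not the truth, so convergence behaviour is honest; the
quasi-Newton optimizer (`nlminb`) runs to a relative tolerance of $10^{-12}$
with at most 500 iterations, and a fit counts as converged when the
transformed-scale gradient max-norm falls below $10^{-5}$ (scaled by the
total sample size for the two-level objective, whose weights are counts).
Non-converged replications are dropped from cell summaries and reported;
a cell with more than 20% failures is flagged.

Standard errors come from the inverse expected (Fisher) information by
default, with Wishart weights $n_g/2$ (single level) and $(n-m)/2$, $(m-1)/2$
(two level). A sandwich estimator (`se = "robust"`; expected-information
bread, per-observation or per-cluster score meat) is available; with exactly
normal data the two differ materially only under model misspecification,
and in the probed design cells the expected-information Wald test tracked
the published rejection rates at least as closely, so it is the default —
consistent with treating plain ML as the estimator of record.

The moderation test is the Wald statistic
$W = \widehat{\Delta\gamma}^2 / \widehat{\mathrm{var}}(\widehat{\Delta\gamma})$
on one degree of freedom, the variance obtained from the estimate covariance
by the delta method on the linear contrast. The likelihood-ratio alternative
(`lrt = TRUE` in the harness) refits each replication with the slope
constrained equal; it costs one extra fit per scheme and replication, which
is why it is opt-in, and the two tests are verified to agree on large
samples.

## Evaluation metrics

Per design cell and scheme, the harness reports the rejection percentage of
the Wald test at $\alpha = 0.05$ (Type I error when the slopes are truly
equal, power otherwise) and the standardized bias
$\bigl[\mathrm{mean}(\widehat{\Delta\gamma}) - \Delta\gamma\bigr] /
\mathrm{SD}(\widehat{\Delta\gamma})$, where the SD uses the population form
(divisor $R$, following the study's printed formula; $|$bias$| < 0.40$ is
the conventional acceptability threshold). An empirical Type I error rate
from 500 replications counts as unbiased within the closed interval
[3.4%, 7.3%] — the printed Monte Carlo band, used verbatim even though it is
asymmetric around 5%. `etaSquared()` decomposes a per-replication outcome
over the design factors with a main-effects-only ANOVA
($SS_{\text{factor}}/SS_{\text{total}}$); the unit of analysis for such
summaries is ambiguous in the source material, so the convention is stated
here and the quantity is informational only.

## A worked cell

```{r}
cnd <- study1Condition(pNI = 2, gamma = c(0.5, 0.5), location = "X", N = 200)
res <- runCondition(cnd, reps = 50, baseSeed = 42)
res[, c("scheme", "converged", "rejectWald", "stdBias")]
```

Fifty replications are enough to see the pattern (the shipped analyses use
$R = 500$): the invariance-assuming model rejects the true null too often
and underestimates the contrast, while the partial model stays near the
nominal level. The direction of the distortion is deterministic and
population-level — predictor-side non-invariance pulls
$\widehat{\Delta\gamma}$ down, outcome-side pushes it up:

```{r}
fit <- fitSEM(populationMoments(cnd), fullMetricScheme())
waldContrast(fit)["delta"]
```

## Problem sizes and runtime

The test suite runs each reproduced design cell at the study's full
$R = 500$ replications (a cell takes on the order of ten seconds to a
minute, dominated by $500$–$1000$ constrained fits), property sweeps over
all 72 grid cells at the population level, and large-sample checks at
$N = 2\times10^5$ observations and $4\times10^4$ clusters. The
`scripts/acceptance.R` driver re-runs the eleven headline cells from
scratch at $R = 500$.

## Known limitations

- Only metric (loading) non-invariance is modelled; scalar and strict
  invariance violations are out of scope.
- The two shipped model topologies are exactly those of the study designs;
  the constraint machinery is general but no user-facing syntax for
  arbitrary SEMs is provided.
- No fit indices (CFI/RMSEA/SRMR) are computed.
- Two-level fitting requires balanced clusters (the sufficient-statistic
  likelihood exploits balance); unbalanced designs are rejected.
- Robust standard errors use the plain sandwich without small-sample
  corrections; at $m = 30$ clusters they are mildly anticonservative, one
  reason the expected-information default is preferred.
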