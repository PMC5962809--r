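# invarimod

Monte Carlo machinery for a question that quietly underlies every
multiple-group moderation analysis: **what happens to the test of a latent
moderation effect when measurement invariance is assumed but does not
hold?**

In multiple-group SEM a moderation effect with a categorical moderator is
the difference of a structural slope between two groups,
Δγ = γ₁ − γ₂. Fitting that model routinely constrains the factor loadings
equal across groups (metric invariance, "MI"). If in truth some loadings
differ — say two or four of six indicators load 0.7 in group 1 but 0.3 in
group 2 — the constrained fit misattributes the measurement difference to
the structural part: Δγ̂ becomes biased (downward for predictor-side,
upward for outcome-side non-invariance), the Wald test of H₀: γ₁ = γ₂
rejects true nulls far too often, and power moves in whichever direction
the bias pushes it. Freeing exactly the non-invariant loadings (partial
metric invariance, "pMI") repairs all of it. This package implements the
whole simulation pipeline that quantifies these statements, for

- a **single-level** two-group model: two latent factors with six
  indicators each and a structural regression F_Y = γ_g F_X + ζ, over a
  40-cell grid of non-invariance degree, slope pairs, non-invariance
  location and sample size; and
- a **two-level** two-group model: a six-indicator latent predictor
  measured at the within- and between-cluster level with equal loadings,
  an observed within-level outcome, and a cross-level moderation contrast
  on the within slope γ₁₀, over a 32-cell grid of non-invariance, slopes,
  intraclass correlation, cluster count and cluster size.

Everything is built in: population parameterizations with validity-checked
(non)invariance structure, model-implied covariance algebra, seeded
generators, constrained normal-theory ML with analytic gradients
(equality constraints by parameter sharing, marker loadings fixed at 0.7),
expected-information and sandwich standard errors, Wald and LRT contrasts,
and a replication harness that assembles empirical Type I error / power /
standardized-bias tables. The methods vignette
(`vignettes/invariance-and-moderation.Rmd`) documents the models, every
numerical choice, and the package's own design decisions.

## A worked example

One design cell: N = 200 per group, true slopes γ = {0.5, 0.5} (no
moderation), two non-invariant predictor loadings. Fifty replications for
illustration — the study-scale runs use 500:

```r
library(invarimod)
cnd <- study1Condition(pNI = 2, gamma = c(0.5, 0.5), location = "X", N = 200)
res <- runCondition(cnd, reps = 50, baseSeed = 42)
res[, c("scheme", "converged", "rejectWald", "stdBias")]
#>   scheme converged rejectWald   stdBias
#> 1     MI        50          8 -0.669213
#> 2    pMI        50          6 -0.106992
```

Both models were fitted to the same 50 replicates. The invariance-assuming
model (MI) rejects the true null in 8% of replications and carries a
standardized bias of −0.67 (beyond the |0.40| acceptability threshold); the
correctly specified partial model (pMI) is essentially unbiased. The bias
is not sampling noise — it has a deterministic population-level value,
obtained by fitting the MI model directly to the population-implied
moments:

```r
fit <- fitSEM(populationMoments(cnd), fullMetricScheme())
waldContrast(fit)["delta"]
#>   delta
#> -0.0704
```

so in this cell the invariance assumption shifts the moderation estimate by
−0.07 on average even though the true contrast is zero. Full grids run with
`runStudy(study = 1, reps = 500, baseSeed = 42)` (72 result rows: one per
cell and fitted scheme) and are written/reread losslessly with
`writeResults()` / `readResults()`; `writeResults(..., layout = "wide")`
produces a publication-style cell-by-scheme table. A thin command-line wrapper
lives at `inst/scripts/invarimod.R`.

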