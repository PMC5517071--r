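---
title: "Testing epistasis from censored patient survival data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing epistasis from censored patient survival data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survlrt)
```

## The model

Tumors of different genotypes differ in fitness, and fitter tumors kill
faster. survlrt turns that observation into a statistical test. Let $G(t)$
be the survival function of a reference population (people who did not die
of the disease under study), and let $g \in \{0,1\}^n$ be a genotype over
$n \in \{2,3\}$ genes, with bit $i$ set when gene $i$ is deleted in the
tumor. The survival of patients whose tumor has genotype $g$ is modelled as
a Lehmann alternative

$$G_g(t) = G(t)^{\Delta_g}, \qquad \Delta_g > 0,$$

so $\Delta_g$ acts as the tumor's fitness: the larger it is, the lower the
patient's survival at every time point. If deletions act independently,
fitness is log-additive, and in particular for any of the thirteen
catalogued epistasis conditions — one pairwise and twelve triple types,
each an ordered genotype quadruple $g_0 < g_1 < g_2 < g_3$ with
$g_0 - g_1 - g_2 + g_3 = 0$ — independence forces
$\Delta_{g_0}\Delta_{g_3} = \Delta_{g_1}\Delta_{g_2}$. The epistatic
effect size is the deviation from that identity in log fitness,

$$\delta = \log\Delta_{g_0} - \log\Delta_{g_1} - \log\Delta_{g_2} +
\log\Delta_{g_3},$$

negative for synthetic-lethality-like interactions (the double-deletion
tumors are less fit than expected, so those patients live longer than
expected) and positive for the opposite. Conditional types `a`–`f` fix one
gene across the quadruple: for genes $(A, B, C)$, type `a` tests the
$A{\times}B$ interaction among patients with $C$ intact and type `b` among
patients with $C$ deleted. That pair of tests is exactly what a
therapeutic-biomarker question looks like: a synthetic lethality present
under type `a` but absent under type `b` means mutation of $C$ masks the
interaction.

## Estimation and the likelihood ratio test

Patients are grouped by genotype into the four quadruple groups (all other
genotypes are excluded from that test). Deaths contribute a density term
and censored patients a survival term, so the log-likelihood collapses to
the sufficient statistics $S_k$, the death count of group $k$, and
$H_k = \sum_i \log G(t_i) \le 0$, the summed log reference survival over
*all* members of group $k$ at their observed times:

$$\ell(\Delta) = \sum_{k=0}^{3} \left[ S_k \log\Delta_k + \Delta_k H_k
\right].$$

The unconstrained maximisers are $\hat\Delta_k = -S_k/H_k$. Under the null
constraint $\Delta_0\Delta_3 = \Delta_1\Delta_2$, substitution of
$\Delta_3 = \Delta_1\Delta_2/\Delta_0$ and stationarity in the remaining
three parameters reduce the problem to a quadratic in $\Delta_1^C$, using
the reparametrisation $\tilde S_0 = S_0 - S_3$, $\tilde S_1 = S_1 + S_3$,
$\tilde S_2 = S_2 + S_3$:

$$H_1(H_1 H_2 - H_0 H_3)\,x^2 +
\left[H_1 H_2 (2\tilde S_1 + \tilde S_0) + H_0 H_3 (\tilde S_2 - \tilde
S_1)\right] x + H_2 \tilde S_1 (\tilde S_1 + \tilde S_0) = 0,$$

with back-substitutions $\Delta_2^C = (\tilde S_1 - \tilde S_2 + H_1
x)/H_2$, $\Delta_0^C = -(\tilde S_0 + \tilde S_1 + H_1 x)/H_0$ and
$\Delta_3^C = x\,\Delta_2^C/\Delta_0^C$. When both roots give parameters in
$(0,\infty)^4$ the one with the higher log-likelihood is kept (exact ties
go to the root closest to the unconstrained $\log\hat\Delta_1$, a
deterministic rule for a measure-zero case); when neither does, a numeric
constrained optimiser (BFGS over the three free log-parameters with
analytic gradient) takes over. The same optimiser serves as an independent
oracle in the test-suite: on large batches of random sufficient statistics
the closed form must match its log-likelihood to $10^{-6}$ relative and
satisfy the constraint to $10^{-10}$, which protects the quadratic's
coefficients against transcription drift.

The test statistic is

$$-2\log\lambda = 2\sum_k \left[ S_k
\log\frac{\hat\Delta_k}{\Delta_k^C} + H_k (\hat\Delta_k - \Delta_k^C)
\right] \;\sim\; \chi^2_1 \text{ asymptotically,}$$

and the simulation suite checks that censoring does not break the
chi-squared calibration. Values in $(-10^{-6}, 0)$ from floating-point
rounding are clipped to zero; anything more negative raises an error, since
it would mean the constrained fit beat the unconstrained one.

A test needs $S_k \ge 1$ and $H_k < 0$ in every group. When a genotype is
absent or contributes no deaths — common for strictly synthetic-lethal
pairs, whose double mutants vanish from tumors — the result is returned as
*inapplicable* with the offending group named, rather than as an error, so
screens can skip and record it. Observations at $t = 0$ contribute
$\log G(0) = 0$ to $H_k$; a group made only of such observations is
likewise inapplicable.

## The reference survival function

`survlrt_ref` stores $G$ as a right-continuous step function: probability 1
before the first knot, each tabulated value held to the next knot, and the
last value held beyond support. Published life tables carry months,
cohort files carry days; days are converted at $12/365.25$ months per day
before any evaluation. Two conventions are ours rather than forced by the
estimator: evaluation between and beyond knots (right-continuity with the
last value held) and the probability floor. Tabulated zeros would make
$H_k = -\infty$, so they are clamped to `floor_prob`, half the smallest
positive tabulated probability. Sampling from $G^\Delta$ uses the inverse
transform restricted to the knot grid — the returned time is the first knot
where $G(t)^\Delta$ drops to the uniform draw — which makes simulated data
live on exactly the support the estimator sees.

## What the simulator emulates

The generator reproduces the design of the package's own validation
experiments:

* **Reference survival.** The default `synthetic_reference()` is a
  Weibull-type step function on a monthly grid (scale 150 months, shape
  1.2, truncated at 480 months), a plausible all-cause-mortality curve for
  an elderly cohort: median survival just over nine years, mean around
  twelve. The mean matters: with censoring drawn from a truncated
  exponential on $[0, 480]$ months, the *lowest* reachable censored
  fraction is roughly the mean observed time over 480, and this choice
  keeps both studied censoring levels (33% and 66%) reachable.
  `exp_reference()` provides the exponential alternative used to check
  that conclusions do not hinge on the shape of $G$.
* **Censoring.** $Y \sim$ truncated $\mathrm{Exp}(c)$ on $[0, 480]$
  months; the observation is $\min(T, Y)$ and the patient is censored when
  $Y < T$. The rate $c$ for a target mean censored fraction is found by
  exact quadrature on the knot grid ($P(Y<T) = \sum_j P(T = t_j)\,F_Y(t_j)$,
  mixed over the genotype groups actually present) and a root finder, so no
  Monte-Carlo tuning noise enters the design.
* **Genotypes.** Per-gene carrier counts are binomial at the gene's
  deletion frequency (default 0.15 per gene, a typical rate for recurrently
  deleted genes) and carriers are chosen uniformly. The quadruple of the
  chosen type gets fitness $(\Delta_0, \Delta_1, \Delta_2, \Delta_3)$,
  default $(1, e^{0.2}, e^{0.3}, e^{0.5+\delta})$; genotypes outside the
  quadruple get the log-additive extension implied by per-gene effects.
  Those patients are excluded by the test, so the extension cannot move the
  statistic; it only completes the landscape. `biomarker_landscape()`
  instead specifies all eight triple genotypes directly, with an
  interaction active only while the third gene is intact — the structure a
  therapeutic biomarker produces.

Three experiments wrap this machinery. `recovery_experiment()` simulates
single groups at $\Delta = 1$ and records $\log(\Delta_{\mathrm{true}} /
\hat\Delta)$: kept-censored estimation is median-unbiased, while dropping
censored cases conditions on $T < Y$ and biases fitness upward, more
severely at 66% than at 33% censoring. `power_experiment()` maps p-values
over effect sizes and cohort sizes. `null_calibration()` checks the
$\chi^2_1$ law of the statistic under $\delta = 0$. Default problem sizes
(200 recovery replicates, 500 calibration replicates, power grids of a few
dozen replicates per cell at cohort sizes 3,000 and 10,000) are the
package's chosen desk-scale defaults; every experiment is deterministic
given `set.seed()`.

The simulator deliberately does **not** emulate several features of real
pan-cancer data: cancer-type heterogeneity in baseline survival (the very
confounder `cancer_bias_check()` diagnoses), linkage between neighbouring
genes deleted as one region (regions enter only through
`group_regions()`), genotype-dependent censoring, and survivorship
depletion of lethal double mutants. A clean pass of the simulation suite
therefore shows the estimator, the constrained fit, and the decision rules
are correct under the model's own assumptions — not that real cohorts
satisfy those assumptions.

## Screening choices

* **Multiple testing.** Benjamini–Hochberg within each epistasis-type
  family separately (the type-`a` screen and the type-`b` screen are each
  their own family); a `bh_family = "joint"` switch corrects their union
  instead, since either reading is defensible.
* **Biomarker rule.** A candidate third gene is called when type `a` is
  significant *and* negative after adjustment while type `b` is not
  significant (insignificant means adjusted $p$ above `alpha`, default
  0.05).
* **Regions.** Genes with byte-identical deletion columns provably give
  identical tests, so one representative per region is tested before any
  p-value is computed, and membership is reported. This is cheaper than,
  and equivalent to, grouping by equal p-values afterwards.
* **Cancer-type bias.** The $q_{gc} = w_g v_c$ product-of-margins check is
  reported (maximum absolute deviation plus a scatter against $y = x$), not
  used as an automatic filter: deviation flags a test for inspection.
* **Concordance filter.** Deletion calls require copy-number loss and
  lower expression in carriers. Whether the published comparison was
  carriers-versus-rest or carriers-versus-everyone is ambiguous; the
  default is the cleaner two-sample carriers-versus-rest, with
  `compare = "all"` available.
* **Mutual-exclusivity baseline.** `sof_score()` is a deliberately simple
  standardised co-deletion deficit under the hypergeometric null. It is an
  approximation of selection-based exclusivity scores from the wider
  literature and is documented as such; comparisons against it should stay
  qualitative.

## Worked example

```{r example}
set.seed(1)
ref <- synthetic_reference()
cohort <- simulate_cohort(
  n = 10000, genes = c("A", "B", "C"), type = "a",
  mut_freq = c(0.3, 0.3, 0.25), censor_frac = 0.66,
  ref = ref, landscape = biomarker_landscape(effect = -2)
)
fit_a <- test_epistasis(cohort, c("A", "B", "C"), "a", ref)
fit_b <- test_epistasis(cohort, c("A", "B", "C"), "b", ref)
glance(fit_a)
glance(fit_b)
screen_biomarkers(cohort, c("A", "B"), "C", ref)
```

Type `a` comes out strongly negative and significant, type `b`
insignificant: gene `C` is called a biomarker of the planted interaction.

## Known limitations

Survival data cannot reveal interactions whose double mutants never reach
diagnosis; effect sizes detectable at current cohort sizes are modest, and
the power study shows cohorts around $10^4$ patients are needed for small
$\delta$. The model adjusts for no covariates and offers no confidence
intervals for $\delta$ (only the test and the point estimates). Censored
cases should be kept: the drop-censored mode exists to demonstrate the
bias, not for analysis.
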