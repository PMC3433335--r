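---
title: "Network Perturbation Amplitude scoring: models, statistics and design choices"
author: "npascore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network Perturbation Amplitude scoring: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npascore)
```

## The scoring model

A HYP couples one upstream biological entity to the downstream genes it is
known to regulate, each with a regulation sign $s_i \in \{+1,-1\}$. Scoring
asks: given per-gene differential statistics for one treated-versus-control
contrast, how strongly — and in which direction — did the process the HYP
describes move?

The statistical model underneath all four scores is that each log2 fold
change estimate $\beta_i$ is approximately normal with variance $sd_i^2$,
where $sd_i$ is the reported standard error carrying $df_i$ degrees of
freedom (the output of a per-gene t or moderated-t analysis). Genes are
treated as independent. The four scores trade off robustness against
sensitivity:

* **Strength** $= \frac1N \sum_i s_i \beta_i$ assumes incoherent
  ("noise") genes cancel in the mean. It is linear and unbiased but a
  systematic bias in $\beta$ propagates directly.
* **GPI** $= \frac1{\sqrt N}\sum_i s_i\, \mathrm{fndr}_i\, \beta_i$ weights
  each gene by its false non-discovery rate
  $\mathrm{fndr}_i = 1 - \mathrm{fdr}_i$, the BH-adjusted p-value computed
  over **all measured genes** (the transcriptome-wide multiplicity, not the
  HYP subset — the adjustment answers "how credible is this gene's change
  in this experiment", which is an array-wide question). Low-confidence
  genes are shrunk toward zero.
* **MASS** $= \sum_i s_i(\mathrm{treated}_i - \mathrm{control}_i) \big/
  \sum_i (\mathrm{treated}_i + \mathrm{control}_i)/2$ works on the linear
  abundance scale for technologies where absolute changes are the
  meaningful quantity. Averaging treated and control in the denominator
  makes the score exactly antisymmetric under swapping the two conditions.
* **EPI** builds a density on the saturation interval $[-M, M]$ from the
  correctly-signed values $x_i = s_i\beta_i$: for $\varphi > \varepsilon$
  the density is proportional to
  $\frac{1}{NM}\sum_{x_i > \varphi} |x_i|$, symmetrically for
  $\varphi < -\varepsilon$, with linear interpolation across
  $[-\varepsilon, \varepsilon]$; the score is the expectation of $\varphi$.
  Genes with strong coherent changes are counted at many thresholds, so
  they dominate — a smoothed, fndr-free analogue of GPI.

### Design choices where the definitions left room

These were genuinely open choices; the package fixes them as follows.

* **GPI normalization.** GPI divides by $\sqrt N$, not $N$. This is the
  scale on which the Taylor-expansion variance
  $Sd_{GPI}^2 = \frac1N \sum_i \gamma_i^2 sd_i^2$ is consistent with the
  score, and it preserves the geometric reading of GPI as a projection onto
  the unit sign vector $\hat s = s/\sqrt N$.
* **EPI density uses magnitudes and unit mass.** The cumulated evidence at
  threshold $\varphi$ sums $|x_i|$ on both sides, so the density is
  non-negative by construction, and by default the density is normalized to
  integrate to 1 on $[-M, M]$. That normalization is what makes the stated
  bound $|EPI| \le M$ a theorem (the expectation of a probability density
  supported on $[-M,M]$). An alternative convention multiplies the
  unnormalized density by $1/(2M)$ instead; it is available as
  `npaEpi(..., literalPrefactor = TRUE)` but does not guarantee the bound,
  so it is off by default.
* **GPI variance weights.** The per-gene weight is
  $\gamma_i = \mathrm{fndr}_i + 2\,(\mathrm{fdr}_i/p_i)\,(|\beta_i|/sd_i)\,
  f_{t,df_i}(|\beta_i|/sd_i)$, i.e. the derivative of
  $\mathrm{fndr}(\beta)\,\beta$ holding the BH adjustment factor
  $\mathrm{fdr}_i/p_i$ fixed (its own derivative matters only at very small
  p and is set to zero). The magnitude form $|\beta_i|/sd_i$ is what the
  derivative actually produces for a two-sided p-value — a signed form
  would make $\gamma$ negative for down-regulated genes, which the unit
  tests' finite-difference oracle rejects. When $\mathrm{fdr}_i = 0$ the
  weight collapses to $\gamma_i = 1$.
* **Ambiguity is dropped, not resolved.** A gene curated with both signs
  under one upstream entity (or contributed with contradictory adjusted
  signs by several network nodes) carries no usable direction; it is
  removed from the scored set and reported, both at HYP load time and at
  network aggregation. Robustness of score profiles to removing 20 % of a
  HYP's genes (see `robustnessExperiment()`) is the empirical justification
  that dropping a few percent of ambiguous genes does not distort results.
* **Missing genes reduce N.** HYP genes not measured in the contrast are
  dropped with the count reported, rather than imputed at $\beta = 0$:
  imputation would shrink Strength and bias the MASS denominator in
  different directions, whereas dropping keeps every score a statement
  about the genes actually observed.

## Uncertainty

Strength is a weighted sum of approximately normal terms, so its interval
is analytic: $Sd^2 = \frac{1}{N^2}\sum sd_i^2$, with effective degrees of
freedom from the Welch–Satterthwaite equation
$Df = (\sum w_i^2 sd_i^2)^2 / \sum (w_i^2 sd_i^2)^2/df_i$ at weights
$w_i = 1/N$, and the interval is the usual
$\pm t_{Df}^{\alpha/2} \cdot Sd$. GPI follows the same route with weights
$\gamma_i/\sqrt N$.

MASS and EPI are not linear in $\beta$, so their intervals come from a
parametric bootstrap: $\beta_i^* \sim N(\beta_i, sd_i^2)$ independently,
rescore, repeat $B$ times (default $B = 2000$; at least 100). Because both
statistics are median-biased under resampling noise (EPI visibly so — the
double-noised replicates up-weight spuriously large values), the interval
is the **bias-corrected percentile** interval: $z_0 = \Phi^{-1}(\text{frac
of bootstrap scores below the observed score})$, endpoints at bootstrap
quantiles $\Phi(2z_0 \mp z_{1-\alpha/2})$. Acceleration is not estimated.
Method-specific resampling: MASS re-derives abundances around the observed
per-gene geometric mean $g_i = \sqrt{\mathrm{treated}_i\,
\mathrm{control}_i}$ as $g_i 2^{\pm\beta_i^*/2}$ (non-negative by
construction, so the zero-truncation guard is never exercised); GPI
replicates recompute the raw p-value from $\beta^*/sd$ and reuse the
observed BH adjustment factor, consistent with the variance approximation
above.

Numerical guards: when all bootstrap scores fall on one side of the
observed value, the bias fraction is clamped to $1/(2B)$ (resp.
$1-1/(2B)$) to keep $z_0$ finite; with all $sd_i \to 0$ the bootstrap
degenerates and the interval collapses onto the point score.

## Specificity

A high score could reflect a data-set-wide trend rather than the HYP's
particular genes. The specificity test replaces each HYP gene with a
different measured gene of similar *modulability*, approximated by the
number of distinct upstream controllers curated for the gene: all measured
genes are ranked by controller count (ties broken lexicographically) and
cut into cadres of 100 (the trailing remainder merges into the final,
fewest-controller cadre, which therefore holds 100–199 genes). Each of the
`nNull` (default 1000) comparable HYPs draws, within each cadre, distinct
replacement genes — never the gene being replaced — and keeps the original
signs. The two-tailed p doubles the lesser of the strict tail fractions
(ties count to neither tail), capped at 1; p = 0 is reported as
"< 1/nNull" in the log. Sampling without replacement within one comparable
HYP (and independently across them) was an open choice; it matches the
"same size, same composition profile" intent and guarantees the null HYPs
are valid HYPs (distinct genes). A naive all-genes null
(`matched = FALSE`) is included only as a comparison mode: most array genes
never move, so it exaggerates specificity.

## The synthetic-data generator

`syntheticSpec()` fixes the simulated study conditions; the defaults are
the conditions under which the statistical guarantees in the test suite are
stated: a 2000-gene universe, a 100-gene HYP with 25 % negative signs,
true amplitude 1, noise scale 0.5, error degrees of freedom 10, log2
baseline 7 (SD 1.5), controller counts geometric with mean 5.

The generative model is $\beta_i = a\,s_i + \sigma Z_i$ with the *reported*
standard error $sd_i = \sigma\sqrt{\chi^2_{df}/df}$ drawn independently per
gene. This choice makes the two halves of the model internally consistent:
$\beta_i$ is exactly normal (the assumption behind the analytic intervals
and the parametric bootstrap), while $\beta_i/sd_i$ is exactly
$t_{df}$-distributed under the null, so the simulated p-values are exactly
uniform for background genes. Simulating the error itself from a
t-distribution with a *fixed* reported $sd$ would instead make $\beta_i$
marginally t-distributed and provably degrade the coverage of the
(correctly computed) intervals to about 92 % at $df = 10$ — a property of
that simulation design, not of the estimator. Abundances are split
symmetrically around the per-gene baseline so that
$\log_2(\mathrm{treated}/\mathrm{control}) = \beta_i$ exactly, keeping MASS
meaningful.

What the generator does **not** emulate: probe-level microarray artifacts,
correlated genes (co-regulation makes effective N smaller than nominal N,
so real-data intervals are somewhat anti-conservative), signal-dependent
variance, or any structure of specific published data sets. Passing the
simulation-based tests therefore demonstrates the estimators are correct
under their own assumptions — not that those assumptions hold on any
particular array experiment.

`syntheticNetwork()` builds causally consistent random networks (a random
signed spanning tree plus shortcut edges whose signs agree with the
tree-implied node signs, so all cycles have even negative parity) and
`corruptNetwork()` plants one parity-breaking edge to produce guaranteed
negative-feedback cases; the consistency checker must accept the former
and reject the latter for every seed.

`syntheticHypSet()` writes four deterministic HYP tables that are
**synthetic stand-ins** for the four reference HYPs this framework is
usually exercised with (an NF-κB-direct set, an aggregated IKK/NF-κB
signaling set, a TNF response set, an E2F1-direct set). They reproduce the
published structural facts — 155, 992, 1741 and 80 unique kept downstream
genes, 247 curation statements behind the 155, an overlap of exactly 32
genes between the TNF and E2F1 sets, ambiguous-gene fractions of roughly
4/6/7/2.5 % — with generated gene identifiers. They exist so parsing,
merging, ambiguity handling and overlap counting can be validated end to
end without redistributing curated content.

## Numerical choices

* **EPI integration is exact.** The density is a step function between the
  sorted distinct $|x_i|$, so mass and first moment are closed-form sums
  per segment; the $[-\varepsilon,\varepsilon]$ interpolation strip
  contributes its exact trapezoid mass and $O(\varepsilon^2)$ moment.
  Default $\varepsilon = M \cdot 10^{-12}$ (order of machine precision
  relative to the scale M). The unit tests verify the closed form against
  an independent oracle that evaluates the density pointwise from its
  definition and integrates piecewise, to $10^{-6}$ over 1000 random
  inputs.
* **Saturation.** $|s_i\beta_i| > M$ (default $M = 15$, the log2 scale at
  which array signal saturates) is clamped to $\pm M$ with a warning rather
  than an error: M is a physical saturation bound, and a value beyond it
  carries no extra evidence.
* **Degenerate inputs.** All-$\beta$-zero EPI returns 0 (symmetric
  degenerate density); an all-zero MASS denominator is an error; an empty
  aligned gene set is an error at alignment time.
* **Determinism.** Every stochastic operation takes an explicit seed and
  restores the caller's RNG state; the command-line tool derives
  sub-seeds from one master seed, and re-running any subcommand with the
  same configuration and seed reproduces outputs byte-identically.
* **Tie-breaking.** Probe-set selection breaks geometric-mean ties
  lexicographically by probe identifier; cadre ranking breaks
  controller-count ties lexicographically by gene; both purely for
  determinism.

## Problem sizes used by the validation suite

The test and acceptance runs state their guarantees at desk scale, chosen
so the full suite completes in a few minutes while keeping Monte Carlo
error well below the tolerances tested: amplitude recovery and bootstrap
coverage use 1000 replicates (universe 300, HYPs of 50–60 genes, B = 800
inside the coverage loop and B = 4000 for the width comparison);
specificity calibration and power use 200 runs of 1000 comparable HYPs
each on the default 2000-gene universe; the robustness experiment uses
1000 subsampling replicates over a 9-contrast profile with true amplitudes
0 to 2 in steps of 0.25.

## Known limitations

* Gene independence is assumed throughout; correlated downstream genes
  inflate the nominal effective N of the analytic intervals.
* The fndr is operationally $1 - \mathrm{BH\text{-}fdr}$; no
  empirical-Bayes local false discovery estimation is attempted.
* Causal inconsistency (negative feedback) is surfaced as an error with an
  offending edge named; resolving it is a biology-driven model edit, not an
  automated graph operation, so no edges are removed silently.
* Scores are comparable across contrasts for a fixed HYP, not across HYPs
  (different gene sets have different dynamic ranges) nor across methods
  (different scales: Strength per gene, GPI per $\sqrt N$, MASS relative,
  EPI in log2 units).
* Probe-set collapsing operates on precomputed per-probe statistics; the
  upstream linear-model refit after collapsing is the data producer's
  responsibility.
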