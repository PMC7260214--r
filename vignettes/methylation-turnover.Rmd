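---
title: "Inferring DNA methylation turnover rates from decay time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring DNA methylation turnover rates from decay time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methkinetics)
```

## The model

DNA methylation at a CpG is treated as a two-state chemical system:
unmethylated cytosines gain methylation at a de novo rate $k_{me}$ (per day)
and methylated cytosines lose it at a demethylation rate $k_{de}$. At
equilibrium the methylation fraction is

$$M_{eq} = \frac{k_{me}}{k_{me} + k_{de}},$$

so an average methylation level fixes only the *ratio* of the rates: 50%
methylation means $k_{me} = k_{de}$, whether both are fast (high turnover) or
slow. Separating the two requires perturbing the system. The experimental
design this package models is induced genetic deletion of the de novo
methyltransferases DNMT3a/b in mouse embryonic stem cells, after which
methylation decays toward zero and the decay curve reveals the absolute rates.

Deletion is not instantaneous: alleles are excised over days and residual
RNA/protein persists. The forward model therefore dampens the de novo rate
exponentially,

$$\frac{dm}{dt} = k_{me}\,e^{-k_E t}\,(1 - m) - k_{de}\, m,
\qquad m(0) = M_{eq},$$

with a single global dampening rate $k_E$. If maintenance were lost
instantaneously, methylation would halve every cell cycle; with a 16-h
doubling time that bounds the loss rate at $\log(2)/(16/24) \approx 1.04$ per
day. Because neither transcript nor protein loss is instantaneous, the default
is half that, $k_E = 0.5$ (the main-text rounding of the bound to 1.03 gives
the same halved default; `model_config(k_E = )` exposes it).

Two corrections map the latent solution onto what bisulfite sequencing
observes:

* **Incomplete excision** — on average 8% of alleles escape Cre excision, so
  the observed trace is a mixture: $y \mapsto 0.92\,y + 0.08\,y_0$ with $y_0$
  the day-0 level. We take $y_0$ as the *uncorrected* steady state (the
  mixing happens at the population level, before measurement error).
* **Conversion error** — 99.75% bisulfite conversion efficiency enters as the
  symmetric miscall transform $y = (1 - 2\varepsilon)x + \varepsilon$ with
  $\varepsilon = 0.0025$.

Corrections are applied in this order (mixture first, then measurement
error); they do not commute in general, and this ordering reflects the causal
chain cell population → library → sequencer.

## Error models

Counts at coverage $n$ are linked to an expected level $p$ by either a
binomial model (adequate for capture data at ≥50×) or a reparameterized
beta-binomial with over-dispersion $\gamma$,
$\alpha = p(1/\gamma - 1)$, $\beta = (1-p)(1/\gamma - 1)$, under which
$\mathrm{Var}(c) = np(1-p)\,(1 + (n-1)\gamma)$. At amplicon depth (~4000×) the
binomial error is far smaller than replicate-to-replicate scatter, and the
$\sqrt{p(1-p)\gamma}$ dispersion floor dominates. `fit_gamma()` recovers
$\gamma$ by a sweep ($\gamma = 0$ plus 100 log-spaced values in
$[10^{-5}, 0.1]$; the sweep range and the decile stratification by coverage
and mean level are package choices — the procedure minimizes the sum of
squared differences between per-stratum pooled replicate standard deviations
of methylation *fractions* and the model prediction). The amplicon default is
$\gamma = 0.0055$.

## Brute-force Bayesian inference

Rates are estimated on a multiplicative grid: 80 values per axis from 2
downward in exact 10% steps (three orders of magnitude), 6400 $(k_{de},
k_{me})$ combinations. For each combination the forward model yields an
expected trace at days 0, 4, 8, 10, 13, 17, 29; the likelihood of one
replicate is the product of per-day count probabilities; the posterior is the
normalized likelihood (uniform prior on the grid). Per replicate we report
the MLE combination and, from each marginal, a central 95% credible interval
(equal tail mass trimmed on the ordered grid), whose width is expressed in
log10 rate units so that widths are comparable across the multiplicative
grid. The choice of a *central* rather than highest-density interval is a
design decision; on the near-unimodal marginals seen in practice the two
rarely differ by more than a grid step.

A fit is **identifiable** only when both marginals place less than a
threshold of probability on the extreme grid value at each border (0.08 for
data fits, 0.05 for the landscape); border mass signals that the optimum lies
outside the parameter space. Replicates are combined by the median of the
MLEs and the standard-error rule
$ci = \sqrt{\sum_i ci_i^2}/r$, and a CpG is identifiable only if every
replicate is.

Numerical notes: likelihoods are accumulated in log space and stabilized by
subtracting the maximum before exponentiation; exact posterior ties are
broken toward the lower total rate $k_{de} + k_{me}$ (with a message); the
beta-binomial kernel exploits $\alpha + \beta$ being constant across the grid
so only two `lgamma` calls per (combination, timepoint) depend on the data.

The ODE is integrated with an adaptive Dormand–Prince 5(4) scheme at
rel/abs tolerance $10^{-8}$, vectorized over all 6400 combinations. deSolve is
not a dependency; the integrator is validated in the test suite against the
closed form for $k_E = 0$, the pure-decay solution for $k_{me} = 0$, and an
integrating-factor + quadrature oracle for the dampened case.

## The identifiability landscape

`compute_landscape()` runs the inference on noise-free pseudo-data from every
grid combination (expected counts at the amplicon median coverage
$n = 3997$, rounded half-to-even; rounding is configurable because the
reference procedure does not state a rule) with three identical
pseudo-replicates and the 0.05 border rule. Four regimes emerge: a central
high-confidence basin; an unidentifiable wedge of unmethylated CpGs (high
$k_{de}$, low $k_{me}$ — flat traces near zero carry no rate information);
inflated intervals for 50%-methylated CpGs with very low rates; and, for
highly methylated CpGs, precise $k_{de}$ with imprecise $k_{me}$ (the
methylation ceiling hides the de novo rate). Globally $k_{de}$ is easier to
infer than $k_{me}$, which is one step removed from what the assay measures.

## TET activity from steady states

In a TET triple-knockout (TTKO) only passive demethylation operates; in wild
type, TET oxidation adds to $k_{de}$. Assuming $k_{me}$ is shared between
backgrounds, the steady-state relation gives

$$\hat k_{de}^{WT} = k_{de}^{TTKO}\,
  \frac{m_{TTKO}(1 - m_{WT})}{(1 - m_{TTKO})\,m_{WT}},$$

an estimate requiring no wild-type time course, and TET activity is the fold
change $\log_2 \hat k_{de}^{WT} - \log_2 k_{de}^{TTKO}$. Steady states at
exactly 0 or 1 make the odds undefined; such CpGs are clipped $10^{-6}$
inward and flagged (or rejected, with `clip = FALSE`).

Wild-type time courses show a transduction-protocol drift visible in
mock-treated samples. `mock_normalize()` removes it: CpGs are binned by mock
day-0 level in 10% increments (half-open bins $[0, 0.1), \dots, [0.9, 1]$),
per-bin mock means at each day are divided by the bin's day-0 mean to give
factors $f_{bin}(t)$, and Cre-treated levels are **divided** by the factor.
The reference description of the final step ("multiplying by the baseline
adjusted value") is ambiguous about direction; division is the direction that
cancels the documented upward drift, and a `direction` switch exposes the
alternative. Corrected levels are re-expressed as counts at the original
coverage so the downstream fit is unchanged.

## The synthetic cohort generator

`cohort_spec()` / `simulate_counts()` generate the only data the package
ships with. The generator emulates exactly the assumptions of the analysis:
per-CpG rate pairs (log-uniform across the grid range, a two-arm steady-state
mixture mimicking the bimodal methylome, or fixed), the dampened forward
model with the 8% excision mixture and 0.0025 conversion error, optional
per-timepoint drift applied to every condition, negative-binomial coverage
(mean 4000 amplicon-like or ~80 capture-like; the reference reports a median
of 3997 and a ≥50× filter but no distribution, so dispersion `size = 10` is a
package choice), and binomial or beta-binomial count sampling via the
two-stage beta-then-binomial construction. Draws are CpG-major from one
seeded stream, so a cohort is bit-reproducible and enlarging `n_cpgs`
preserves the prefix.

What a green test therefore establishes: the estimator is correct *under its
own model* — coverage of credible intervals, recovery of grid-valued rates,
recovery of $\gamma$, and the TET round trip all hold on data generated by
the stated forward model. What it does not establish: robustness to features
real bisulfite data have and the generator omits — spatially correlated
errors between neighboring CpGs, strand asymmetry and hemimethylation,
hydroxymethylation (indistinguishable from 5mC in bisulfite data),
read-level conversion failure, PCR duplicates, or mapping artifacts.

## Filtering rules

`filter_counts()` implements the assay rules: amplicon calls need 100×
coverage (failing calls become NA); a replicate series is dropped if day 0 is
NA or more than one timepoint is NA. The reference wording "more than one NA
during the time course across all replicates" is ambiguous; the rule is
applied per replicate series by default, and `joint = TRUE` drops the whole
CpG when any series fails. Capture data require 50× at every timepoint and
replicate. Attrition is reported so input→output accounting is reproducible.

## Known limitations

* Rates are grid-quantized; no off-grid optimization or MCMC is attempted,
  so no estimate can be more precise than a 10% step.
* The dampening rate $k_E$ is global, not per-CpG, and is not inferred.
* The TET estimator attributes the whole $k_{de}$ fold change to "TET
  activity"; it cannot separate bona fide active demethylation from impaired
  maintenance of oxidized cytosines.
* The landscape assumes identical pseudo-replicates; real replicate scatter
  enters only through the error model's $\gamma$.

## A minimal run

```{r example, eval = FALSE}
cfg <- model_config()
spec <- cohort_spec(20, "loguniform", coverage_mean = 4000, seed = 1)
counts <- simulate_counts(sample_true_rates(spec), spec, cfg,
                          error_model("betabinomial", 0.0055))
est <- fit_rates(counts, cfg, error_model("betabinomial", 0.0055))
head(est)
```
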