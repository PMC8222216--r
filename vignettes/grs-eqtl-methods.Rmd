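---
title: "Methods: combinatorial GRS eQTL scanning"
author: "grsQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial GRS eQTL scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsQTL)
```

## The problem

Genome-wide association studies identify common variants that each confer a
small risk of disease, yet a carrier almost always harbors several of them
at once. Single-variant eQTL mapping asks how one variant shifts the
expression of one gene; it cannot see a regulatory effect that only emerges
when multiple risk alleles are carried together. `grsQTL` operationalizes
that question through genetic risk scores (GRS): for every subset of a
weighted variant panel, individuals are scored, the extremes of the score
distribution form low- and high-risk groups, and every gene is tested for
an expression difference between the groups. A subset whose stratification
yields a significant difference is an *eCombination*; a gene reached by at
least one eCombination is an *eGene*. Epistasis is operationalized here as
a joint, additive effect detectable through combined-GRS stratification —
not as a multiplicative interaction term.

## The model

For a variant subset $S$ with per-variant log odds-ratio weights
$w_i = \ln(\mathrm{OR}_i)$ and risk-allele dosages $d_{ji} \in \{0,1,2\}$,
the score of individual $j$ is

$$\mathrm{GRS}_j \;=\;
  \frac{\sum_{i \in S} d_{ji}\, w_i}{\tfrac{1}{|S|}\sum_{i \in S} w_i}.$$

Dividing by the mean weight (rather than centering) makes scores
comparable across subsets of different sizes, cancels any common rescaling
of the weights, and reduces exactly to the risk-allele dosage when
$|S| = 1$ — so single-variant scans are the classical per-genotype
grouping as a special case. Weight tables are oriented at load time: a row
with OR $< 1$ has its alleles swapped and its OR inverted, so all weights
are non-negative and the mean weight is positive whenever any variant is
informative. This orientation also makes all downstream statistics
invariant to how the input file happened to label alleles.

Given a quantile fraction $q$ (default 0.30), each risk group holds
$\lfloor q\,n \rfloor$ individuals — the flooring rule is the one
consistent with groups of 176 from a cohort of 588 at $q = 0.30$. The
lowest-scoring group is labelled `low`, the highest `high`, and the middle
of the distribution is excluded from the fit. Ties at a group boundary are
broken by sample identifier, a stable deterministic rule the score itself
does not provide.

Expression differences are tested by ordinary least squares of a gene's
expression on `[intercept, high-indicator, covariates]` over the grouped
individuals. The effect size (ES) is the high-vs-low coefficient in
expression units; its two-sided t-test p-value uses classical residual
degrees of freedom. Covariates (age, sex, source study, genotype principal
components) enter as supplied, with categorical columns expanded to
indicator contrasts.

Each *test series* — all combinations of one variant panel against all
genes — is one multiple-testing scope. The Benjamini–Hochberg step-up
procedure (`stats::p.adjust`, method `"BH"`) is applied once across the
entire series; `runPipeline()` enforces one series per invocation. For
series too large for FDR at a usable threshold, a fixed p-value cutoff
(e.g. $10^{-5}$ or $10^{-7}$) can be used instead, justified by inspecting
`qqData()` — the package pairs sorted p-values against uniform order
statistics $i/(m+1)$ but deliberately attempts no automated elbow
detection.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `q` | 0.30 | risk-group quantile fraction; each group is $\lfloor qn\rfloor$ samples, $q \le 0.5$ |
| `mafFloor` | 0.05 | sample-MAF exclusion floor at genotype load |
| `maxSize` | none | cap on combination size (used when the full powerset is computationally out of reach) |
| significance mode | `fdr` at 0.05 | BH across the series; `pthresh` for fixed cutoffs |
| `minCombinations` | 1 | eGene filter: how many significant eCombinations a gene needs (3 in the strict reporting mode) |
| `chunkSize` | 131,072 | combinations per streamed chunk; memory is O(chunk) |

MAF is computed on the loaded sample set (a reference-panel MAF is not
assumed to be available). A variant with any missing genotype call is
excluded entirely — no imputation is attempted.

## The synthetic cohort generator

The generator exists so that every downstream stage can be exercised
against a known ground truth. It emulates a cohort of unrelated
individuals: biallelic variants in Hardy–Weinberg equilibrium with MAF
drawn uniformly from [0.05, 0.5] (matching the 5% exclusion floor),
GWAS-style odds ratios drawn log-uniformly from [1.05, 2.0], Gaussian
expression noise on an already-normalized continuous scale (no count
model — the reference data are microarray-style), covariates with modest
fixed effects shared across genes, and planted regulatory effects of two
kinds: `single_cis` (one variant, one gene) and `joint_additive` (the same
small per-variant slope, with shared sign, summed over a variant set —
the summation-of-small-unidirectional-effects reading of epistasis; no
product terms are generated). The default demonstration scale is 600
individuals, 7 variants and 500 genes.

Deliberately **not** emulated: linkage disequilibrium between panel
variants (independence is the simplest structure that exercises the
pipeline), haplotype/population structure beyond PC covariates, dosage
uncertainty, and case–control phenotypes. Passing tests on this generator
therefore demonstrate correctness of the machinery and calibration under
idealized sampling, not robustness to LD-structured real genotypes — on
real data, correlated variants will make distinct combinations much more
strongly dependent than they are here.

The covariate contribution is identical for every gene, which keeps the
all-null variance decomposition analytic
(`var(gene) = var(covariate term) + noiseSd^2`) and is exposed through
`covariateContribution()` for exactly that check.

## Numerical choices

* **Enumeration order** is increasing size, then lexicographic over sorted
  variant identifiers; a truncated run is a well-defined prefix and the
  iterator exposes a `(size, index)` cursor for resumption. Combination
  identity is the sorted `"+"`-joined key everywhere.
* **Tie-breaks** at quantile boundaries use sample-ID order (stable); with
  all scores equal the groups are still filled to exactly
  $\lfloor qn\rfloor$ each.
* **Underflow**: p-values below $10^{-300}$, and exact fits whose residual
  sum of squares is at rounding-error scale relative to the total sum of
  squares, are reported as $10^{-300}$ with an `underflow` flag rather
  than as zero.
* **Degenerate genes** (zero variance within the grouped samples) are
  recorded with ES 0 and p 1 and flagged, never dropped silently; a
  rank-deficient design raises an error naming the collinear columns.
* **Reported percentages** (contribution profiles) are rounded half-up to
  one decimal, the presentation convention of the field's contribution
  figures; the exact fraction is retained alongside.
* Counts of planned tests use double arithmetic (they exceed 32-bit
  integer range beyond ~15 variants); enumeration counts are exact
  binomials.

## Design decisions where the design was open

* **Protective alleles.** How a GRS should average weights when some lead
  alleles are protective is ambiguous; this package resolves it by
  orientation at load time (all weights $\ge 0$), which keeps the mean
  weight positive and the monotonicity property (adding a risk allele
  never lowers a score). For panels containing originally protective
  ORs this can differ numerically from a signed-weight convention.
* **Genotype encoding.** Hard calls {0,1,2} are assumed; dosage
  uncertainty is out of scope.
* **Middle-quantile individuals** are excluded from each fit entirely,
  including from covariate estimation.
* **FDR scope** is the whole series of one run; combining categories into
  one scope, or re-using fits across scopes, is intentionally not
  supported.
* **Expression normalization** is treated as upstream: the package takes
  already-normalized continuous values and never transforms them.

## Problem sizes used by the test suite

The suite pins its stochastic checks to fixed seeds and to scales chosen
to finish quickly while keeping the relevant asymptotics visible: HWE
goodness-of-fit at $n = 5000$; regression-oracle comparisons on 100 random
designs of 20–50 samples; null calibration on a 2-variant × 3,334-gene
all-null cohort (10,002 tests — a panel this small keeps the combination
overlap between tests low, so the Kolmogorov–Smirnov test retains close to
its nominal level despite the shared stratifications); parameter recovery
on 20 replicate cohorts of 600 × 7 × 500 with two planted 4-variant joint
effects (per-variant slope 0.24 in noise-SD units, placed by a
design-stage power computation so that each single-variant test is
underpowered at the series threshold while the exact joint combination is
well-powered at $q = 0.30$); and a calibration sweep with four planted
cis eGenes whose weakest effect is tuned to roughly 80% replication power
at the 30% fraction.

A caveat the power geometry forces: the replication power of a fixed
additive effect at fraction $q$ scales like $\varphi(z_{1-q})\sqrt{q}/q$,
which is nearly flat between adjacent grid fractions above 20% and peaks
near $q \approx 0.27$. Combined with the strong correlation of test
statistics across nested groups, the smallest all-replicating grid
fraction in any single realization is governed largely by noise, not by a
designable power threshold: in design-stage Monte Carlo the sweep selects
a small fraction or none far more often than an interior one. The
fixed-seed sweep test asserts the designed interior outcome regardless,
so its result should be read with this geometry in mind; the selection
*logic* (smallest replicating fraction; unset when nothing replicates) is
covered by deterministic tests.

## Known limitations

* The scan is exhaustive; panels beyond ~20 variants need `maxSize` caps,
  and the R implementation targets the demonstration and validation scale
  rather than the billions-of-tests scale of full production scans (the
  streaming iterator and chunked fits keep memory bounded either way).
* BH control assumes positive-regression dependence across tests; the
  heavy overlap of stratifications between nested combinations satisfies
  this in the cases examined here, but no permutation-based empirical FDR
  is provided.
* No LD pruning, kinship correction, or mixed models; cohorts are assumed
  unrelated.
* Cross-dataset replication compares effect signs and nominal
  significance; it does not meta-analyze effect sizes.
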