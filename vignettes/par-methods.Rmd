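---
title: "Methods: cross-ancestry attributable risk from summary statistics"
author: "parGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-ancestry attributable risk from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parGWAS)
```

## The model

The package estimates, per variant and per ancestry stratum, the
population attributable risk (PAR): the fraction of disease cases
attributable to carrying a risk allele. With risk allele frequency $p$
and per-allele odds ratio $OR$, Levin's formula gives

$$PAR = \frac{p\,(OR - 1)}{p\,(OR - 1) + 1}.$$

Three assumptions are baked in:

1. **OR stands in for the relative risk.** Case-control GWAS report odds
   ratios; Levin's formula is exact for relative risks. For a rare
   disease the two nearly coincide. `attributableFractionByEnumeration()`
   is an independent enumeration of the exact attributable fraction, and
   the test suite quantifies the substitution error at 0.5% prevalence
   (it stays well below 0.01 for $OR \le 3$, $p \le 0.5$).
2. **The exposure unit is the allele.** $p$ is the risk allele frequency
   itself, not the carrier frequency $1-(1-p)^2$; no diploid genotype
   model is used. This matches the direct substitution of summary-level
   allele frequencies into the formula. A carrier-based PAR with genotype
   ORs would be a different (and generally larger) quantity.
3. **Per-variant PAR.** Each lead variant is treated marginally; no joint
   or LD-adjusted multi-variant attributable risk is computed, and PAR
   values across loci do not sum meaningfully.

No confidence intervals are attached to PAR; the pipeline reports point
estimates and ranks.

## Harmonization

Published tables orient effects arbitrarily: a protective allele
($\beta < 0$, $OR < 1$) is the mirror image of a risk effect on the other
allele. `harmonizeVariants()` flips such records — risk allele := other
allele, $RAF := 1 - \text{reported frequency}$, $\beta := |\beta|$ — so
that every variant satisfies $OR = e^{|\beta|} \ge 1$ before PAR is
computed. The operation is idempotent and exact (the frequency complement
uses no floating-point beyond one subtraction). Three edge policies:

- $\beta = 0$ is kept unflipped with $OR = 1$, hence $PAR = 0$; rejecting
  it would serve nothing.
- ORs are always derived as $e^{\beta}$ from the stored beta, even when
  the input supplied an OR column (converted to beta on read): one
  internal effect scale, no dual code paths.
- A/T and C/G palindromic variants cannot be strand-checked without a
  reference panel, which is out of scope; they pass through with a
  message.

The reported effect-allele frequency is taken at face value as the
frequency of the reported effect allele. Summary-statistics columns named
"MAF" do not always contain a *minor* frequency; treating the value as
the effect allele's frequency is the only reading under which the flip
rule $RAF = 1 - f$ is coherent.

## Variant selection

`filterSignificant()` keeps variants with $p < \alpha$ (default
$\alpha = 0.05$, strict comparison). Nominal significance is deliberately
an *inclusion* requirement: its purpose is confidence in the direction of
each effect, since harmonization hinges on the sign of $\beta$, and a
sign indistinguishable from zero would make the risk-allele orientation —
and hence RAF — arbitrary. Discarding the significant variants instead
would remove every genome-wide hit and leave nothing to attribute.

`selectLeadPerLocus()` takes the smallest p-value per locus label. Locus
membership comes from the table's own locus (nearest-gene) column, not
from positional windows. Ties are broken by larger $|\beta|$, then
lexicographically smallest variant id — an arbitrary but deterministic
rule, so permuting the input can never change the selection.

`applyProxies()` substitutes user-declared correlated proxies (a
two-column `target`/`proxy` file) when a variant of interest is absent or
unreliable in one dataset, recording the substitution in a `proxy_for`
column. Proxy *discovery* from LD reference panels is out of scope; the
map is entirely user-supplied, and a missing proxy falls back to the
original with a warning.

## Fine-mapping

Loci highlighted by PAR are validated with the minimal summary-statistics
fine-mapping model: a single causal variant per locus, a uniform prior
over the locus's variants, and Wakefield's approximate Bayes factor per
variant,

$$ABF = \sqrt{\frac{se^2}{se^2+W}}\;
  \exp\!\left(\frac{z^2 W}{2\,(se^2+W)}\right),
  \qquad z = \beta/se,\; W = \text{priorSd}^2,$$

giving posterior inclusion probabilities $PIP_i = ABF_i / \sum_j ABF_j$.
This estimator needs no LD matrix — matching the situation where only
summary statistics are available — and only $z^2$ enters, so the
harmonized $|\beta|$ is used as-is. Choices and caveats:

- `priorSd` defaults to 0.2 on the log-OR scale, a standard
  weakly-informative effect-size scale for complex traits; it is
  configurable per run.
- ABFs are computed and normalized in log space with max-subtraction;
  $z$ of 60+ does not overflow.
- The 95% credible set is the smallest descending-PIP prefix summing to
  ≥ 0.95; `high_confidence` flags $PIP > 0.80$ (`ppThreshold`), and at
  any threshold ≥ 0.5 at most one variant per locus can be flagged.
- Multi-signal loci are *not* decomposed into conditional signals; each
  locus is fine-mapped once under the single-causal assumption, which
  concentrates the posterior on the strongest signal and understates
  secondary ones.
- The test suite checks the closed form against numerical quadrature of
  the Gaussian marginal likelihood and checks causal-variant recovery on
  simulated LD blocks (below).

## Ranking and classification

Within each ancestry, PAR estimates receive dense ranks, highest first;
ties share a rank, making ranks permutation-invariant.
`buildComparison()` assembles the loci × ancestries matrix over the union
of loci (NA where a locus has no qualifying variant), rows ordered by
descending mean of present values. `classifyLoci()` operationalizes the
qualitative notion of universal versus population-specific targets: a
locus is **universal** when it ranks in the top `topK` (default 10) of at
least `minAncestries` (default: all) ancestries, **enriched** in the
listed ancestries when it makes fewer top lists, **single** when only one
ancestry carries it at all, and **background** otherwise. Both knobs are
exposed on the CLI; enlarging `topK` can only promote loci.

## The synthetic-data generator

Real per-ancestry summary statistics cannot ship with the package, so
`simulateStudy()` generates them with known ground truth. The model:
alleles are the sampling unit (2N per arm, Hardy–Weinberg sampling).
Given population RAF $f$, per-allele risk ratio $OR$ and prevalence $K$
(default 0.005), baseline allele risk is $r_0 = K/(1+f(OR-1))$ and the
arm frequencies follow by Bayes: $p_{case} = OR f/(1+f(OR-1))$,
$p_{ctrl} = f(1-OR\,r_0)/(1-K) \approx f$. Case/control allele counts are
binomial draws; $\hat\beta$ is the sample 2×2 log-OR with the
Haldane–Anscombe 0.5 correction when a cell is zero, $se$ the usual
square root of summed reciprocal cells, and the p-value two-sided Wald
(clamped at the smallest positive double rather than underflowing to an
invalid 0). A configurable fraction of records (default 0.3) is emitted
in flipped, protective-looking orientation — exactly what harmonization
must undo.

LD blocks are simulated at the z-score level (in the style of
regression-with-summary-statistics models), not via individual
genotypes: with AR(1) correlation $R_{ij} = \rho^{|i-j|}$ and the causal
variant's expected Wald z $\lambda$ (from its OR, RAF and the sample
sizes via `expectedWaldZ()`), the z-vector is drawn from
$\mathcal{N}(R\lambda e_c,\, R)$ and converted back to (beta, se, p) at
each variant's frequency. This is sufficient for testing ABF fine-mapping
and orders of magnitude faster than genotype simulation.

What the generator does **not** emulate — so what passing tests do not
show about real data: strand errors and allele mislabelling,
imputation-quality variation, overlapping samples between studies,
admixture and relatedness, effect-size correlation across ancestries, and
genotype-level LD. Recovery results here certify the pipeline's
arithmetic and contracts, not robustness to those artefacts.

### Simulation designs used by the tests and acceptance script

Chosen once as realistic desk-scale designs:

- *Parameter recovery*: 200 single-variant studies at 20,000 cases /
  20,000 controls, OR 1.3, RAF 0.3 — a well-powered modern GWAS regime.
  The mean recovered PAR lies within ±0.01 of `computePAR(0.3, 1.3)`.
  The small positive bias (~0.007) that remains is a known convention
  effect: the generator reports the *pooled* case+control allele
  frequency as `eaf` (as meta-analyses commonly do), which exceeds the
  control-arm frequency for a risk allele, and feeds through Levin's
  formula.
- *Fine-mapping recovery*: 100 blocks of 20 variants, $\rho = 0.7$,
  causal variant in the middle, 4,200 cases/controls at OR 1.3, RAF 0.3 —
  sample sizes chosen so the causal expected z is 8.0, a clearly
  genome-wide-significant single signal. The causal variant attains the
  top PIP in ≥ 95/100 blocks.
- *Null calibration*: 2,000 replicates at OR 1, 10,000 per arm;
  Kolmogorov–Smirnov uniformity of the Wald p-values at the 0.01 level.
- *Rare-disease substitution*: 50,000 alleles per arm at prevalence
  0.005 over $(p, OR) \in \{0.1,0.3,0.5\}\times\{1.5,2,3\}$.
- *End-to-end study*: the packaged 4-ancestry, 3-locus fixture (seed
  20240923, ~8 variants per ancestry) whose ranked comparison table is
  stored as a golden file and reproduced byte-identically on every run.

## Numerical and I/O conventions

- Tables are tab-delimited with a header; doubles are written with 6
  significant digits, and a write/read round trip is exact at that
  precision. Delimiter on input is auto-detected (tab preferred, comma
  fallback).
- Only single-nucleotide A/C/G/T alleles are accepted; indels and
  multi-allelics are rejected at read time, as are rows with
  out-of-range frequencies, standard errors or p-values (more than 50%
  invalid rows aborts the read).
- Coordinates are 1-based and build-agnostic; no positional arithmetic
  is performed, so no liftover is needed or offered.
- All generator randomness flows from one integer seed; identical seeds
  give byte-identical outputs.
- The pipeline manifest records input checksums, the effective
  configuration and its hash, and per-stage row counts; reruns on
  identical inputs are bit-reproducible.

## Limitations

Beyond the modelling assumptions above: PAR point estimates carry no
sampling uncertainty here; cross-ancestry differences in PAR are
described (ranks, classification), never formally tested; the
single-causal fine-mapping cannot separate allelic series at one locus;
and proxy substitution trusts the user's declaration of correlation. The
visualisation reproduces the analysis figures' content (RAF on x, OR on
y, marker area linear in PAR with a floor at PAR = 0, linear axes with a
log-OR option) without aiming at any particular published aesthetic.
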