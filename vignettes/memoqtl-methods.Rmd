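---
title: "Methylation-moderated eQTL mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-moderated eQTL mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memoqtl)
```

## The statistical model

`memoqtl` tests whether the methylation level of a CpG site *moderates* a
SNP–expression relationship. For one (SNP, CpG, gene) triple over $n$
samples, three nested ordinary-least-squares models are fitted on identical
complete cases:

$$
\begin{aligned}
\mathrm{M1}:\; & \mathrm{Gene} = \alpha_1 + \beta_1\,\mathrm{SNP} + \varepsilon_1\\
\mathrm{M2}:\; & \mathrm{Gene} = \alpha_2 + \beta_{21}\,\mathrm{SNP} + \beta_{22}\,\mathrm{meCpG} + \varepsilon_2\\
\mathrm{M3}:\; & \mathrm{Gene} = \alpha_3 + \beta_{31}\,\mathrm{SNP} + \beta_{32}\,\mathrm{meCpG} + \beta_{33}\,\mathrm{SNP}\times\mathrm{meCpG} + \varepsilon_3
\end{aligned}
$$

The SNP enters as additive dosage $\{0,1,2\}$, methylation as the continuous
beta value in $[0,1]$, and expression as the rank-based inverse normal
transform of FPKM, which makes the Gaussian error assumption reasonable and
immunizes the fit against expression outliers. Model comparison uses the
likelihood ratio statistic $2(\ell_{\text{full}} - \ell_{\text{reduced}})$
with the Gaussian maximum-likelihood log-likelihood
$\ell = -\tfrac{n}{2}\{\log(2\pi\,\mathrm{SSE}/n) + 1\}$, referred to a
$\chi^2$ distribution (df 1 for M3 vs M2, df 2 for M3 vs M1). The
$\chi^2$ reference is the classical LRT; at the cohort sizes this package
targets ($n \approx 128$) it is mildly anti-conservative relative to the
exact F test — the synthetic validation quantifies the actual level.

A triple is a **memo-eQTL (G1)** when the M3 overall F-test, the M3-vs-M2
LRT and the M3-vs-M1 LRT are all significant at $\alpha$. Triples passing
the overall gate but failing one LRT fall into **G2** (only M3-vs-M2
significant), **G3** (only M3-vs-M1 significant) or **G4** (neither);
triples failing the overall gate are `not_evaluated`. Two of these rules
were genuinely open and are fixed here as package conventions:

- "M3 is significant" is operationalized as the overall F-test of M3
  against the intercept-only model (an alternative — gating on the
  interaction t-test — would collapse gates 1 and 2 into one).
- The G2/G3 labels are assigned as above; only G1 has substantive meaning
  (the other groups exist to describe why a gated triple was not called).

## Upstream screens and filters

The defaults encode the standard analysis funnel and are all exposed in
`memoqtl_config()`:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | significance level of every gate |
| `maf` | 0.05 | strict lower bound on minor allele frequency |
| `r2` | 0.8 | LD pruning threshold on squared dosage correlation |
| `window` | 1e6 bp | maximum SNP–TSS distance (inclusive) |
| `mean_range` | [0.25, 0.75] | admissible mean beta of a CpG (inclusive) |
| `cpg_iqr` | 0.1 | strict lower bound on beta IQR |
| `min_median_fpkm` | 1 | expression filter (genes kept at or above) |
| `min_pet` | 15 | chromatin-loop PET filter (inclusive) |
| `B` | 1000 | permutation-null partitions |
| `min_n` | 30 | complete cases required per triple |
| `min_frac` | 0.2 | minimum subsample fraction in the threshold search |

LD pruning is greedy left-to-right within a physical 1-Mbp window: a
variant is dropped iff its $r^2$ with any already-retained variant in the
window reaches the cut. This replaces count-based pruning windows (e.g. 50
SNPs, step 5) with a parameter-free physical rule that is deterministic and
independent of SNP density; its post-condition (no retained pair in the
window with $r^2 \ge$ cut) is asserted against brute force in the tests.

Candidate triples require the CpG *strictly between* the SNP position and
the gene's strand-aware TSS — the geometric precondition for a
loop-mediated moderation mechanism — with the window bound inclusive and
the MAF bound strict (both literal readings of the usual conventions).

Coordinates follow both community standards simultaneously: VCF/feature
positions are 1-based points, BED/BEDPE intervals 0-based half-open, and a
point $p$ lies in $[s,e)$ iff $s < p \le e$. The center of a CTCF site
$[s,e)$ is $\lfloor (s+e)/2 \rfloor + 1$ (floor rather than rounding: a
deterministic choice where no convention exists).

The inverse normal transform uses offset $(r - 0.5)/n$ with average ranks
for ties — symmetric and finite for every rank; the Blom offset
$(r - 3/8)/(n + 1/4)$ is available via `rank_inverse_normal(offset =
"blom")`. The transform is invariant under any strictly monotone
transformation of the input, so expression can be supplied on any monotone
scale (FPKM, TPM, log-counts) without changing downstream inference.

In the CpG–CTCF screen, the Spearman coefficient is the Pearson correlation
of average ranks on pairwise-complete observations and its p-value uses the
t approximation with $n-2$ df — the standard tie-compatible choice at the
screen's scale of a few dozen cell types; an exact permutation p-value
would change nothing the screen's thresholds can detect. Binding sites with
significant pairs of *both* correlation signs are removed wholesale before
one representative (smallest adjusted p, ties by larger $|$SCC$|$, then
leftmost CpG) is kept per site.

## Stratification at the optimal threshold

To visualize and classify a moderation effect, samples are dichotomized at
the methylation threshold $\tau^\*$ that separates the two subsample eQTL
models the most. Candidates are the distinct observed beta values inside
$[Q_1, Q_3]$; membership is relH $= \{\beta \ge \tau\}$, relL
$= \{\beta < \tau\}$; the objective is
$|\log_{10} p_{\mathrm{relL}} - \log_{10} p_{\mathrm{relH}}|$ from the M1
fits in each subsample, with ties resolved toward the smaller threshold.
The absolute log-p difference is the package's own formalization of
"separates the most": it is scale-appropriate for p-values and symmetric in
the two subsamples (an alternative, the difference of slope z-scores, gives
nearly identical optima on well-powered triples). Log p-values are computed
directly on the log scale, so the objective remains well defined when a
subsample association underflows double precision. Candidates leaving
either subsample below `min_frac` of the samples, or with a monomorphic
SNP, are skipped — without this guard the objective rewards tiny, unstable
subsamples.

Subgroups are then assigned by the M1 p-values at $\alpha$: `sigHigh`
($p_{\mathrm{relH}} < \alpha \le p_{\mathrm{relL}}$), `sigLow` (the
reverse), `sigBoth`, `sigNone`.

The variance decomposition uses sequential (type-I) sums of squares in the
order SNP → meCpG → interaction, i.e. exactly the M1 ⊂ M2 ⊂ M3 nesting:
each term's SS is the SSE drop when it enters, so the three fractions are
nonnegative and sum to one by construction. They are invariant to
rescaling of the response.

## The synthetic cohort generator

`simulate_cohort()` emulates the input structure of a matched
genotype/WGBS/RNA-seq cohort: $n = 128$ samples; genotypes Hardy–Weinberg
at MAF 0.3; methylation drawn from Beta(0.5, 0.5) rescaled into
$[0.25, 0.75]$ — a switch-like bimodal law chosen to mimic variably
methylated CpGs at CTCF sites, which pass the mean/IQR filters by
construction; expression generated from the moderated linear model
$y = \beta_0 + \beta_1\mathrm{SNP} + \beta_2\mathrm{meCpG} +
\beta_3\mathrm{SNP}\times\mathrm{meCpG} + \epsilon$,
$\epsilon \sim N(0, \sigma^2)$ with $\beta_1 = \beta_2 = 0.5$,
$|\beta_3| = 1.5$ (alternating sign) for the ten planted triples and pure
noise otherwise, $\sigma = 1$. FPKM is $10\,e^{y}$ — a monotone map, so the
inverse normal transform downstream recovers the latent outcome's ranks
exactly while keeping the FPKM matrix nonnegative and above the
median-expression filter.

The default geometry lays out ten isolated planted blocks (one SNP, CpG,
gene each) and five null blocks of 8 SNPs, 2 CpGs and 4 genes arranged so
each null block contributes 48 admissible triples — 240 null triples in
total, a desk-scale testbed for false-call behaviour. Blocks sit 3 Mbp
apart so the 1-Mbp window never crosses them. ATAC-like peaks cover every
SNP and CTCF-like loops are anchored at the planted CpGs.

What the generator does *not* emulate: LD structure (variants are drawn
independently, so pruning is exercised by planted duplicate columns in the
tests rather than by realistic haplotypes), cell-type composition effects
on methylation, covariate structure (age, ancestry), count noise in
RNA-seq, and meQTL-driven (genotype-correlated) methylation. Passing the
validation suite therefore demonstrates the statistical machinery is
correct and calibrated, not that real cohorts are free of the confounders
the generator omits.

## Validation harness

The validation quantities recomputed by `scripts/acceptance.R` and asserted
in the test suite, with the problem sizes the package adopts for them:

- **Null calibration** — 2,000 combinations with $\beta_3 = 0$,
  $\beta_1 = \beta_2 = 0.5$, $\sigma = 1$, $n = 128$: the M3-vs-M2 LRT
  rejection rate at $\alpha = 0.05$ is required to fall in
  $[0.035, 0.065]$ (the width accommodates the mild anti-conservatism of
  the $\chi^2$ reference plus Monte-Carlo noise).
- **Recovery and power** — 500 replicates per effect size: mean
  $\hat\beta_{33}$ within three Monte-Carlo standard errors of truth;
  G1-call frequency nondecreasing over $\beta_3 \in \{0, 0.5, 1, 1.5, 2\}$.
- **Method comparison** — ten datasets of 5,000 combinations (30 %
  non-null, $|\beta_3| = 1.5$): the p-value-gated rule must find at least
  as many true positives as BH-FDR gating of the interaction p-values.
  This holds deterministically under the package's definition (BH-adjusted
  p-values are never smaller than raw ones and the other gates are shared),
  and the F1/TP numbers quantify the gap.
- **Threshold recovery** — a planted regime switch at beta 0.5
  ($y = 1.5\,\mathrm{SNP} + \epsilon$, $\sigma = 0.1$, only below the
  switch; $n = 200$): $\tau^\* \in [0.45, 0.55]$ across seeds.
- **End-to-end cohort** — the default generator through the full pipeline,
  reporting planted-triple G1 recall and false G1 calls among the 240
  nulls, plus byte-identical reruns under a fixed seed.
- **Permutation null** — a subsample-specific effect ($\beta_1 = 1.5$ in
  relL only, $\sigma = 0.5$, 64/64 split, $B = 1000$) must yield an
  empirical p below 0.05 across seeds; the empirical p uses the plus-one
  rule $(1 + \#\{p_{\text{null}} \le p_{\text{obs}}\})/(1 + B)$ and never
  returns zero.

A note on detection power: with methylation confined to $[0.25, 0.75]$, the
interaction regressor's partial variance is
$\mathrm{var}(\mathrm{SNP})\cdot\mathrm{var}(\mathrm{meCpG}) \lesssim 0.03$,
so at $|\beta_3| = 1.5$, $\sigma = 1$, $n = 128$ the noncentrality of the
interaction LRT is only $\approx 4$ and the per-triple G1 power sits near
one half — the power curve produced by the harness makes this visible.
High per-triple recall at these settings would require larger effects,
larger cohorts, or a wider methylation range; the end-to-end check reports
recall as measured rather than presuming it high.

## Degenerate inputs and numerical conventions

- Missing genotypes/betas are kept at load time; every fit uses the
  complete cases of its own triple, and the three models of one triple are
  always fitted on the *same* samples (required for a valid LRT).
- Monomorphic SNPs, rank-deficient designs, or fewer than `min_n` complete
  cases yield `not_evaluated` results with missing p-values rather than
  errors, so a scan never aborts mid-table.
- A perfect fit (SSE = 0) has infinite Gaussian log-likelihood; LRT and
  F-test p-values degenerate to 0, which is the correct limit.
- Multiallelic or non-SNV VCF records are skipped (not split) with a
  warning; trans-chromosomal BEDPE records likewise.
- `align_cohort()` orders the sample intersection lexicographically; reruns
  are therefore deterministic, and the pipeline writes a version/seed/
  config-hash header on every output so runs are auditable.

## Known limitations

- No covariate adjustment (expression PEER factors, ancestry PCs, cell-type
  proportions): moderation calls on real tissue cohorts should be
  interpreted with the cell-composition caveat above.
- The $\chi^2$ LRT reference is asymptotic; for $n \ll 100$ the F-test
  would be preferable.
- The threshold search optimizes an in-sample objective; $\tau^\*$ is a
  descriptive quantity, and the subsample p-values it reports are not
  corrected for the search.
- Trans associations, phased genotypes and loop calling from raw contact
  data are out of scope; loops are consumed as BEDPE.
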