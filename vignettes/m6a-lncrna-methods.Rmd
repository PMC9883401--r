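---
title: "Methods: screening, ceRNA inference, drug-resistance scoring and validation"
author: "m6aLncTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, ceRNA inference, drug-resistance scoring and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6aLncTools)
```

# Overview

`m6aLncTools` asks three questions of an expression cohort: which lncRNAs
track the m6A regulatory machinery, what do those lncRNAs plausibly do,
and do they matter clinically. This vignette records the models behind
each stage, the parameters that matter, the numerical and design choices
made where more than one defensible option existed, and what the
package's validation does and does not establish.

# Data model and preprocessing

The central container is `M6AExpression`, a `SummarizedExperiment`
subclass holding one dense gene-by-sample assay with a mandatory per-gene
`role` (regulator / lncRNA / miRNA / mRNA) and a scale flag. Two
preprocessing operations are defined only in one direction:

* `filterExpressed(x, minFraction = 0.7)` keeps genes with abundance
  strictly above zero in at least 70% of samples. The threshold is
  inclusive ("at least") and the filter refuses log2-scale input, because
  the pseudocount erases the zero/nonzero distinction the filter is
  defined on.
* `log2Transform(x, offset = 1)` computes log2(TPM + offset). The
  pseudocount is not dictated by any external convention stronger than
  common practice; 1 is the default and it is exposed as a parameter
  because genes surviving the breadth filter can still contain zeros.
  Transforming twice is an error, not a warning.

The 21-gene regulator catalog (11 readers, 8 writers, 2 erasers) ships
with the package (`m6aRegulators()`); regulators absent from a matrix are
skipped with a warning so partially annotated cohorts remain analysable.

# The m6A-relatedness screen

For every (lncRNA, regulator) pair the screen computes the sample Pearson
correlation and the two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. A lncRNA is
m6A-related when $|r| > 0.3$ and the Benjamini–Hochberg adjusted
$q < 0.05$; both inequalities are strict.

Choices worth recording:

* **FDR family.** The default family is all lncRNA-by-regulator tests
  within one cohort (`fdrScope = "cancer"`), because downstream summaries
  are per-cohort landscapes. A per-regulator family is available
  (`fdrScope = "regulator"`); whether a global cross-cohort family would
  be preferable is a judgement call we deliberately leave out, since the
  classification stage consumes per-cohort records.
* **Candidate restriction.** A whitelist of candidate lncRNAs (for
  example, those with prior m6A evidence) can be supplied via
  `candidates`; without one, all lncRNA rows are tested.
* Constant lncRNAs are dropped with a warning; a constant regulator is an
  error, since it silently invalidates a whole screen column.

# ceRNA network inference

Candidate axes come from an experimental interaction catalog: every
(lncRNA, miRNA, mRNA) triple in which the miRNA targets both partners,
with the lncRNA restricted to the m6A-related set — the axis definition
requires the shared miRNA before any correlation is computed. A triple is
retained when r(lncRNA, mRNA) > 0.3, r(miRNA, lncRNA) < −0.3 and
r(miRNA, mRNA) < −0.3, each with q < 0.05. BH adjustment uses two
families per cohort: the miRNA–target correlations (both halves pooled,
as they estimate the same kind of repressive edge) and the lncRNA–mRNA
correlations. Axes naming molecules absent from the matrix are skipped
with a warning because catalog/matrix mismatches are the norm with real
annotation sources.

# The drug-resistance score

For one drug, mRNAs are ranked by the Pearson correlation between their
log2 expression and per-sample IC50 over pairwise-complete samples
(higher IC50 = more resistant cell line). Ties in the metric are broken
lexicographically by gene id so rankings are reproducible. A lncRNA's
ceRNA target set $S$ ($|S| = N_H$) is scored along the ranking
$L = g_1 \dots g_N$ by the weighted Kolmogorov–Smirnov walk

$$P_{hit}(S,i) = \sum_{g_j \in S,\, j \le i} \frac{|r_j|^p}{N_R},
\qquad N_R = \sum_{g_j \in S} |r_j|^p, \qquad
P_{miss}(S,i) = \sum_{g_j \notin S,\, j \le i} \frac{1}{N-N_H}$$

with ES the maximum deviation from zero of $P_{hit} - P_{miss}$.

Numerical and design choices:

* **Absolute values in the weights.** The defining sums are sometimes
  written as $r_j^p$ without bars; with negative metrics and odd $p$ that
  makes $N_R$ ill-defined. The default uses $|r_j|^p$ with $p = 1$, the
  canonical weighted-GSEA convention; `useAbs = FALSE` exposes the raw
  alternative rather than switching silently, and a non-positive $N_R$ is
  an error.
* **Tie-break at the extreme.** When the positive peak and negative
  trough of the walk tie in magnitude — which happens structurally, e.g.
  a single hit exactly mid-list — the positive peak is returned. The tie
  is detected with a 1e-12 tolerance so that floating-point noise cannot
  flip the sign of a genuinely tied score.
* **Walk conservation.** The running sum ends at zero by construction;
  tests assert it to 1e-12 as a guard against weight-normalization bugs.
* **Permutation null.** Significance uses random gene sets of the same
  size (set-label permutation). Re-ranking the genes per permutation
  under a per-sample phenotype shuffle would cost $B$ full rankings per
  pair for an equivalent null here, since the simulated IC50 has no
  sample structure beyond its coupling to expression.
* **Split-null p-value.** Calls are sign-specific, so the p-value is
  estimated against the same-signed portion of the null:
  $p = (1 + \#\{b: \text{same sign}, |ES_b| \ge |ES_{obs}|\}) /
  (1 + \#\{b: \text{same sign}\})$. Dividing the same-sign exceedance
  count by $B+1$ instead would roughly double the type-I error at any
  nominal level (the exceedance side is chosen by the observed sign), and
  the package's calibration test — the fraction of null p-values below
  0.05 must sit in [0.03, 0.07] — rules that variant out. The add-one
  form keeps $p \ge 1/(B+1)$ and an observed ES of exactly zero returns
  $p = 1$.
* **Calls.** BH over all lncRNA-drug pairs of a screen; ES > 0 with
  q < 0.05 is `resistant`, ES < 0 with q < 0.05 `sensitive`, else `ns`.

# Survival analysis

Cohorts are split at each lncRNA's median expression: strictly above
goes high, ties at the median go low, so the median sample is always
grouped the same way. The groups are compared by the log-rank test
(`survival::survdiff`; the statistic depends on times only through
ranks) and by a univariate Cox model (`survival::coxph`, Breslow ties —
ties are rare with continuous simulated times, and Breslow is the
simplest estimator). The default Cox covariate is the high/low indicator
so the hazard ratio matches the grouping narrative; `covariateMode =
"continuous"` fits the expression itself. A group with zero events makes
the log-rank statistic undefined; callers choose between a hard error
(default) and a flagged `NA`. Effectively infinite coefficients are
reported as separation errors rather than returned.

# Sequence features

* `gcContent`: (G+C)/(length excluding N); N is excluded from both
  numerator and denominator.
* `normalizedCpG`: observed CpG frequency over the $L-1$ dinucleotide
  positions, divided by the expected frequency $(GC/2)^2$. The $L-1$
  denominator makes observed and expected commensurate per-position
  frequencies. A zero-GC or single-base sequence has an undefined ratio,
  signalled as `NA` — never 0 or infinity, both of which would silently
  distort group comparisons.
* `motifCount`: IUPAC consensus scan (default DRACH, D=[AGT], R=[AG],
  H=[ACT]; RRACH or any other consensus via `pattern`), overlapping
  matches all counted, U read as T. This is a deliberate consensus-level
  feature, not a site predictor: no classifier score is attached to a
  match.
* `tssNormCpGProfile`: windows of 200 nt at 100 nt steps across ±2 kb
  around each TSS (all three configurable; a flank smaller than the
  window is rejected as invalid geometry), strand-mirrored so positive
  offsets are downstream, clipped at sequence bounds, with undefined
  windows excluded from the mean and counted. The defaults are a
  conventional promoter-profiling geometry; nothing in the method depends
  on them.
* Conservation scores are consumed as an optional per-sequence column,
  never computed.
* Group comparisons use the equal-variance Student's t test for counts
  and scores and the two-sample Kolmogorov–Smirnov test for normalized
  CpG distributions; `NA` feature values must be removed by the caller
  and are an error otherwise, so exclusion decisions stay visible.

One caution: normalized CpG is a ratio, and windows with little GC but
concentrated CpG can exceed the ratio of a pure CpG repeat (a CG-only
window has O/E = 2). Profile peaks should be read with the underlying GC
in mind; the profile table reports per-offset window counts for this
reason.

# Pan-cancer classification

A lncRNA significant in (at least `commonMinFraction` of, default all)
the analysed cancers is cancer-common; in exactly one, cancer-specific
(with that cancer recorded); otherwise intermediate. The common rule
takes precedence if a lenient fraction makes both labels apply. The
default expression-deviation statistic is the between-cancer standard
deviation of per-cancer mean log2 expression, a direct reading of
"stably expressed across tumor types"; a pooled coefficient-of-variation
mode is available. Tissue-elevation enrichment is an upper-tail
hypergeometric test.

# The synthetic-cohort generator

The generator is first-class, tested code; its defaults are the study
conditions every recovery test and the acceptance script run under.

* **Expression.** Latent Gaussians mapped to TPM as $2^{z+4}$ (log-normal
  abundance, median TPM 16). After the pipeline's log2(TPM+1) the values
  are $z + 4$ up to a vanishing correction, so planted Pearson structure
  survives the round trip and every gene passes the breadth filter.
  Planted m6A-related lncRNAs (fraction 0.2 of 60 lncRNAs, by default
  one fifth with negative sign — mirroring the strong dominance of
  positive correlations this kind of screen reports) load on one
  regulator each at $\rho = 0.6$.
* **Sponging triples.** One miRNA per sponged lncRNA, several mRNAs:
  lncRNA and mRNAs each load $-0.6$ on the miRNA and $0.5$ on a shared
  positive latent, giving population correlations $-0.6$ (both miRNA
  edges) and $0.61$ (lncRNA–mRNA). A per-triple independent miRNA would
  be inconsistent at these loadings: $k$ independent miRNAs each at
  $-0.6$ need $0.36k < 1$ of a unit variance. The one-miRNA-many-mRNAs
  shape also matches how single sponged lncRNAs are actually reported.
* **Drugs.** IC50 = unit-weight sum of five effect genes' log2 expression
  plus unit Gaussian noise; effect genes are the ceRNA targets of one
  sponged lncRNA (cycling across drugs), so recovery tests exercise the
  full path from catalog to call. Positive weight = resistance-associated.
* **Survival.** Exponential times with hazard $h_0 e^{\beta x}$,
  $h_0 = 0.002$/day, $\beta = \log 2$ on the above-median indicator of
  the planted lncRNA; independent uniform censoring on $[0, c]$ with $c$
  solved numerically for the target censoring fraction (0.3).
* **Sequences.** First-order composition model at the GC target with the
  C→G transition probability multiplied by the CpG enrichment factor and
  the row renormalized; enrichment above 1 therefore pulls realized GC
  slightly above the target, which the truth table records exactly.
  DRACH 5-mers are spliced in at evenly spaced, non-overlapping recorded
  positions. Truth counts are recomputed post hoc on the emitted strings
  with plain string operations, deliberately independent of the
  Biostrings-based feature module, so the agreement check is a genuine
  dual-route comparison.
* **Determinism.** One master seed; each stage derives its own stream
  through a fixed integer hash, so any stage can be regenerated
  independently and the same design reproduces every output byte for
  byte.

What the generator does *not* emulate: batch effects, missing expression
values, count noise at the low-abundance end, linked miRNA families,
non-proportional hazards, and realistic genomic sequence context.
Passing recovery tests therefore demonstrates correctness of the
inference machinery under the stated generative model, not robustness to
the full messiness of real cohorts.

# Validation problem sizes

The packaged validation uses cohorts of 500 samples for the screen
(1,050 lncRNAs: 50 planted at $\rho = 0.6$, 1,000 null), the ceRNA filter
(20 independent seeds) and the drug score (100 seeds, 200 permutations
per pair); survival calibration uses 200 replicates at $\beta = 0$ and
recovery 100 replicates at $\beta = \log 2$, n = 300. These sizes were
chosen so each estimate's Monte-Carlo error is small against the
acceptance band it is compared to (for example, a rejection-rate
estimate at 0.05 over 200 replicates has standard error 0.015).

# Interfaces

The package is an R API: exported functions plus this vignette are the
operational surface, and the acceptance script under `scripts/` is the
only command-line entry point. Every tabular interchange format is
header-named TSV; sequences are FASTA and TSS annotations BED, read and
written through Biostrings and rtracklayer.

# Known limitations

* The screen is Pearson-only by design; rank or partial correlation and
  covariate adjustment are out of scope.
* FDR families are per-cohort; no cross-cancer meta-analysis statistic
  is computed.
* The drug score reports no normalized ES and no leading-edge genes;
  BH over pairs is the only multiplicity control.
* The Cox model is univariate; no adjustment, stratification or
  time-dependent covariates.
* Enrichment of ceRNA target sets against functional annotation
  databases is intentionally not bundled.
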