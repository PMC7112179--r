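---
title: "Models and methods behind pollenTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pollenTE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pollenTE quantifies two linked phenomena in the maize male gametophyte:
the developmental activation of transposable element (TE) transcription
across pollen development, and the fitness cost of mutations in highly
expressed gametophyte genes, measured as non-Mendelian transmission of a
seed marker. This vignette documents the models, the parameters that
matter, the synthetic-data generators that make the pipeline testable
without sequencing data, and the numerical choices at the edges.

## TE expression quantification

TE-derived reads are heavily multi-mapped. Reads are counted
*fractionally*: a read with $k$ equally best-scoring candidate loci
contributes $1/k$ at each locus (four candidate loci give each TE 0.25 of
a read). Each locus passes its weight to the feature with the largest
overlap; a tie splits the weight equally — the tie rule is a package
choice, since largest-overlap assignment alone does not determine it.
Mass is conserved: assigned plus unassigned weight equals the number of
reads.

Differential TE expression against the seedling reference uses a
deliberately simple negative-binomial Wald test, not a reimplementation
of any published tool:

* counts are rounded to integers at entry;
* per-sample size factors are median-of-ratios to the per-feature
  geometric mean (computed over features detected in every sample),
  rescaled to geometric mean 1; if no feature is common to all samples,
  library-size ratios are used with a warning;
* the NB dispersion is estimated per feature by the method of moments
  *within* each group (so a true fold change does not inflate it), pooled
  by degrees of freedom, and moderated toward the across-feature median
  with 4 pseudo-degrees of freedom. With 3–4 replicates the raw moment
  estimator is extremely noisy; the moderation is what makes the Wald
  statistic usable, in the spirit of empirical-Bayes variance shrinkage;
* the Wald statistic on the log fold change (delta-method standard error)
  is referred to a t distribution with residual + prior degrees of
  freedom; p-values are BH-adjusted over tested features.

Features whose mean normalized count falls below 1 are not tested and
carry `NA` p-values, mirroring the independent-filtering route by which
low-information TEs end up uncalled. Where one group is all zero, a 0.5
pseudo-count guards the reported log2 fold change; the test itself uses
the same stabilized means. The calibration of this stand-in is
characterized by the package's own simulations (under the generator's
null, the raw type-I rate sits near 0.05 and planted four-fold signals at
4 vs 4 replicates are recovered above 90%); those simulations run in the
test suite and the acceptance script, at 800–2,000 features per run.

## The four-way TE partition

Every annotated TE receives exactly one category, with precedence:

1. **near_genes** — gap distance under 2 kb to any gene. Distance is
   measured edge to edge on 1-based inclusive coordinates,
   strand-agnostic; a gap of exactly 2,000 bp is *distal*, because the
   distal analysis set is defined as elements more than 2 kb from genes.
2. **not_covered** — distal, but with a summed raw count below 10 across
   all samples, or an `NA` adjusted p-value in every tissue comparison.
3. **dynamic** — adjusted p below 0.05 in at least one tissue versus the
   seedling reference.
4. **static** — covered but never differentially expressed.

Family composition of a category is summarized as
$\log_2(\text{observed fraction}/\text{background fraction})$, with
"no data" (`NA`) when either count is zero. Persistence of activation
across stages is the fraction of TEs up-regulated at stage A still
expressed at stage B; dataset overlaps are tested with the
hypergeometric upper tail on the shared TE universe.

## Gene expression classes

Gene abundance is FPKM (fragments per kilobase of transcript per million
mapped fragments). Genes are assigned to mutually exclusive classes from
tissue-mean FPKM: *vegetative cell* (top 20% in mature pollen and FPKM
greater in pollen than in sperm cells), *sperm cell* (the converse), and
*seedling* (top 20% in seedling and in the top set of neither pollen nor
sperm). The top-quantile universe defaults to genes with nonzero
tissue-mean FPKM; the all-genes universe is available, since the
denominator is genuinely ambiguous. Rank ties at the quantile boundary
break by feature id so that assignment is deterministic. Genes with
$\log_2(\mathrm{FPKM}) > 8$ in their class tissue carry a very-high
expression flag, the split used in the transmission analyses.

## The binned gene–TE neighborhood statistic

For one tissue, the top 20,000 expressed features (every analysis here
exposes the count and the bin width) are ranked by tissue-mean
expression, ties broken by feature id, and divided into bins of 200. Per
bin, the number of up- and of down-regulated TEs within 2 kb of the bin's
features is summed — a TE near $k$ binned features counts $k$ times — and,
separately, the number of features with at least one such TE is counted
once per feature. The second series controls for multiple counting of
shared neighbors. Monotone association is tested with tie-corrected
Kendall $\tau_b$ between per-bin *median expression* and each count
series; median expression rather than bin index is used because it is
monotone-equivalent for a rank statistic yet robust to bin-width edits.
Per-bin counts tie heavily, hence the tie-corrected variant. A
contamination control re-runs the binning on features expressed strictly
higher in the focal tissue than in a comparison tissue: association that
survives the filter cannot be an artifact of cross-contamination between
the two samples.

In the package's simulation tests the statistic runs at 1,000 ranked
genes in 100 bins of 10 with a TE:gene ratio of 3 — one hundred bins, as
in the full-scale design, with per-bin neighbor counts kept comparable to
a TE-dense genome where roughly 1.5 near-gene TEs accompany each gene.

## Quasi-binomial transmission model

For a heterozygous insertion allele outcrossed through the male, each ear
contributes marked seeds $y_i$ of $n_i$. The working model is
quasi-binomial with logit link: $E(y_i) = n_i\mu$,
$\operatorname{Var}(y_i) = \phi\, n_i \mu(1-\mu)$. For the intercept-only
model the maximum-likelihood rate is the pooled proportion
$\hat\mu = \sum y_i / \sum n_i$ (the IRLS fixed point, used in closed
form). Overdispersion is the Pearson statistic over its degrees of
freedom,

$$\hat\phi = \frac{1}{k-1}\sum_i \frac{(y_i - n_i\hat\mu)^2}{n_i\hat\mu(1-\hat\mu)},$$

pooled by default across all ears of an expression class (degrees of
freedom: ears minus alleles in the class), which stabilizes the estimate
and matches the observation that a class-level dispersion near 1.8
describes the seed data; per-allele estimation is available. Departure
from Mendelian $\mu_0 = 0.5$ is tested with a quasi-likelihood F test,
$F = (D_0 - D)/\hat\phi$ on $(1, \mathrm{df}_{\hat\phi})$ degrees of
freedom, where $D$ is the binomial deviance. With $\phi$ fixed at 1 and
infinite denominator degrees of freedom this reduces exactly to the
binomial likelihood-ratio chi-square test, which anchors its unit tests.
BH correction is applied within expression class and cross direction by
default; a global family is available and is the natural choice when all
alleles are displayed as one experiment.

Ear-level QC implements two rules: an ear is excluded as a candidate
double insertion when its marked fraction exceeds 0.70 *and* an exact
binomial test rejects 0.5 (one-sided, p < 0.01) — the second condition
protects small noisy ears, since a fraction threshold alone is not an
operational rule; and an allele is dropped unless it retains at least
three male ears from at least two plants.

Boundary fits (pooled rate 0 or 1) clip the link at $\mathrm{logit}(10^{-8})$
and flag the result rather than failing, keeping batch analyses alive.

Class-level comparisons build gene-level 2×2 defective/non-defective
tables (a gene is defective if any allele is significant) and use the
Fisher exact test. The `alternative` is exposed rather than fixed: the
class-versus-class proportions reported in this literature are consistent
with one-sided tests even where methods text says two-sided, so both
conventions are first-class. Expression–fitness coupling within a class
is summarized by two ordinary regressions: transmission rate on
$\log_2(\mathrm{FPKM})$, and $-\log_{10}(p)$ on $\log_2(\mathrm{FPKM})$.

## Seed phenotype statistics

Ovules examined a few days after pollination are classified *normal*
(one synergid penetrated, both embryo and endosperm developing) or
*abnormal* (anything else: single fertilization of either product, or
both synergids penetrated); groups are compared with the two-sided Fisher
exact test. Per-ear small-seed fractions (or seedless-area percentages)
are compared treatment-versus-control with Welch t-tests — Welch rather
than pooled variance, as the safer default when ear-to-ear variance
differs between genotypes. Genotype enrichment among sampled small seeds
is tested against a Mendelian sampling expectation of 0.5 with the exact
binomial test; conditioning on the overall transmission deficit is
deliberately ignored, because the comparison of interest is against a
control line, not a formal null.

## What the generators emulate — and what they do not

All generators are pure functions of a configuration and its seed, and
every planted signal is returned as a truth table so recovery tests never
re-derive it.

* `gen_annotation` lays out non-overlapping genes and TEs with an exact
  planted near/distal status (near TEs sit at a uniform 0–1,999 bp gap
  from a host gene, everything else at least 2.5 kb away), a centromere
  per chromosome, and one isoform per gene. Default 18.3% of TEs are
  near genes, the genome-wide proportion for this system.
* `gen_counts` draws log-normal baselines (log-mean log 50, log-sd 1)
  and NB replicates (dispersion 0.1) for four tissues × four replicates;
  TEs are activated (default +2 log2) in the male-lineage tissues, and a
  configurable coupling makes a near-gene TE's activation probability
  rise with its neighbor's expression percentile,
  $p = f\,(1 + \kappa\,\mathrm{pct})$ — one of several mechanisms that
  would produce the observed neighborhood association, chosen for
  transparency, not as a claim about mechanism. $\kappa = 0$ is the
  null. 40% of TEs are near-silent so that the not-covered category is
  populated.
* `gen_ear_counts` draws ear sizes uniformly on 380–1,305 seeds
  (four ears per allele give totals spanning roughly 1,520–5,220) and
  marked counts from a beta-binomial whose intra-ear correlation is
  calibrated as $\rho = (\phi - 1)/(\bar n - 1)$ so the pooled Pearson
  dispersion is about 1.8 at the default ear sizes. The default allele
  panel is 56 alleles at rate 0.5, split 35/11/10 across the vegetative
  cell, sperm cell and seedling classes.
* `gen_phenotypes` draws multinomial ovule outcomes and binomial per-ear
  small-seed counts.

What they deliberately do not emulate: read sequences and mappability
(placements are abstract candidate loci), isoform complexity (one
isoform per gene), genomic clustering of TE families, linkage between the
marker and other loci, maternal/environmental structure beyond the
ear-level beta variance, and the selection bias of an insertion-line
collection against severely defective alleles. Passing recovery tests
therefore demonstrates that the estimators do what they claim under the
stated stochastic model — not that real sequencing or field data satisfy
that model.

## Numerical choices and degenerate inputs

* Exactly-2,000 bp gaps are distal (strict `< 2000` for near); the
  threshold is configurable.
* All rank ties (quantile boundaries, bin edges) break by feature id.
* Fisher tests on tables with a zero margin return p = 1 with a warning.
* All-tied vectors give a flagged `NA` tau instead of an error.
* A single ear cannot support a dispersion estimate; the test demands an
  externally pooled `phi_override`.
* Dispersions are floored at $10^{-8}$; boundary rates are clipped at
  $\mathrm{logit}(10^{-8})$ and flagged.
* The last expression bin may be short; it is kept and flagged.
* BH treats `NA` p-values as untested: excluded from the family size and
  passed through in place.

## Known limitations

The quasi-binomial working model assumes one dispersion for all ears in
a pooling scope, while the beta-binomial generator (constant intra-ear
correlation) makes the true per-ear dispersion grow with ear size. The
F test absorbs most of this, but at the extreme tail the analysis is
mildly anticonservative: across 600 simulated null panels the
probability that a full female-direction control panel shows no
BH-significant allele was 93%, rather than the ~95% an exactly
calibrated test would give. The effect is negligible at the effect sizes
of scientific interest (a rate-0.30 allele is flagged essentially
always) but worth knowing when interpreting borderline adjusted
p-values near 0.05.

The NB Wald stand-in has no fold-change shrinkage and no outlier
handling; with more than ~6 replicates per group or strong count
outliers, a full shrinkage estimator is preferable. The coexpression
statistic deliberately does not address causal direction — read-through
transcription versus shared regulation cannot be separated by binned
counts alone.
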