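---
title: "Methods: transcriptome-wide MR with multi-omic colocalization"
author: "omicsMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome-wide MR with multi-omic colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsMR)
```

## The problem

GWAS variants for cognitive and psychiatric traits concentrate in
non-coding, regulatory sequence, so the natural mechanistic hypothesis
is that they act by changing gene expression — in the brain, the
tissue where these phenotypes arise. omicsMR implements the analytical
machinery for interrogating that hypothesis with summary statistics
only: cis-eQTL instruments feed two-sample Mendelian randomization
(MR) against each outcome, Bayesian colocalization filters out
associations driven by linkage disequilibrium (LD) between separate
causal variants, three-trait colocalization asks whether DNA
methylation sits on the same causal pathway, and downstream modules
cluster effects across outcomes, test gene-set enrichment, compare a
primary tissue against a proxy tissue, and scan the phenome for
pleiotropy.

Every stage is testable without access to cohort data because the
package ships a generator of LD-structured marginal summary statistics
with known causal content (`simulateSummaryStats()`), which is also
the calibration bed for the decision thresholds the pipeline applies.

## Models and estimators

### Two-sample MR

For a gene instrumented by a single independent cis-eQTL, the causal
effect of expression on the outcome is the Wald ratio
$\hat\theta = \hat\beta_{out}/\hat\beta_{exp}$ with first-order
delta-method standard error $se(\hat\theta) = se_{out}/|\hat\beta_{exp}|$.
With $k \ge 2$ independent instruments the per-SNP ratios are combined
by fixed-effect inverse-variance weighting,
$\hat\theta_{IVW} = \sum w_i \hat\theta_i / \sum w_i$,
$w_i = se_i^{-2}$, $se_{IVW} = (\sum w_i)^{-1/2}$.

Two deliberate simplifications, both conventional for cis-MR with few
instruments:

* the first-order Wald se ignores instrument uncertainty. It is a good
  approximation only when the instrument is strong; the exact
  second-order correction is available via `secondOrder = TRUE`. The
  mediation scenario below is parameterized in the regime where the
  first-order interval is honest (see *Calibration choices*).
* fixed-effect rather than multiplicative random-effects IVW: with one
  to a handful of instruments per locus a heterogeneity variance is
  not estimable.

Instruments are selected by greedy LD clumping (`clumpVariants()`):
repeatedly take the smallest-p unassigned variant with
$p \le 5\times10^{-8}$ as an index and absorb everything within the
window at $r^2 \ge 0.01$. Ties in p are broken by larger $|z|$ (p can
saturate the double underflow floor while $\beta/se$ still ranks),
then position, then identifier, making the output deterministic and
independent of record order. Clumping operates on the exposure (QTL)
p-values; the clump window defaults to 1000 kb, consonant with the
1 Mb cis design.

The transcriptome-wide family threshold is Bonferroni over the number
of exposures that actually produced an instrumented, harmonizable
estimate for the outcome at hand — the number of testable genes, not
the number of genes submitted.

### Allele harmonization

Exposure and outcome records are paired on variant id and the outcome
is aligned to the exposure's effect allele; swapped alleles (directly
or after strand complement) negate the outcome beta and complement its
frequency. Palindromic variants (A/T, C/G) carry no strand information
in their allele codes, so the effect-allele frequency decides: pairs
with either frequency missing or inside [0.42, 0.58] are dropped as
ambiguous, otherwise frequency concordance infers the strand. The
operation is an involution — harmonizing an already-harmonized pair
changes nothing — and the MR-relevant product
$\beta_{exp}\beta_{out}$ is invariant to which trait is called the
exposure.

### Pairwise colocalization

A significant MR signal from a single SNP can be produced by two
different causal variants in LD. `colocABF()` therefore computes, over
the shared variants of a cis-region, the posterior probability of five
configurations — no association (H0), either trait alone (H1, H2), two
distinct causal variants (H3), one shared causal variant (H4) — from
per-variant Wakefield approximate Bayes factors
$\log ABF = \tfrac12\log(1-r) + rz^2/2$, $r = W^2/(se^2+W^2)$.
Effect priors are $W = 0.15\,sd_Y$ for quantitative traits and
$W = 0.2$ on the log-odds scale for binary ones; configuration priors
default to $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$. All sums run in
log-sum-exp arithmetic; the H3 term (sum over ordered distinct pairs)
is the product of the per-trait totals minus the coincident diagonal,
computed as a signed log-space difference and clamped at zero, so no
$O(m^2)$ loop and no catastrophic cancellation. The pipeline calls
"colocalized" a locus with $PP_{H4} > 0.8$; $PP_{H4}$ alone, not
$PP_{H3}+PP_{H4}$.

Variants are intersected by id without allele alignment: the ABF
depends on $z^2$ only, so flipping signs cannot change posteriors, and
dropping ambiguous palindromes would only discard information.

### Three-trait colocalization

For loci passing the MR + colocalization filter, the package asks
whether proximal DNA methylation shares the same causal variant as
expression and outcome. A configuration chooses which traits are
associated and partitions them into groups sharing one causal variant
each: 15 configurations for three traits (1 null + 3 singles + 6 pair
patterns + 5 three-trait partitions; `enumerateConfigs()` supports
k = 4 for combinatorial checking only). A configuration's likelihood is
the product over groups of a per-cardinality prior
($10^{-4}$ single-trait, $10^{-6}$ two-trait, $10^{-7}$ three-trait)
times the sum over assignments of *distinct* variants to groups of the
product of grouped ABFs. Distinct-assignment sums are evaluated
exactly by inclusion–exclusion over per-group log-sum-exp totals — for
three groups,
$S_1S_2S_3 - S_1D_{23} - S_2D_{13} - S_3D_{12} + 2D_{123}$ in signed
log arithmetic — so cost is linear in the number of variants. The
headline quantity `ppaFull` is the posterior of the single
configuration in which all three traits share one variant, not a sum
over partial sharings (a configurable choice).

`scanCpgs()` repeats the analysis over every CpG within 100 kb
(inclusive) of the gene's coordinates and reports the per-CpG table
together with the maximal `ppaFull`; no multiplicity adjustment is
applied over CpGs, by design — the table is emitted so users can apply
their own.

### Conditional signal decomposition

Where clumping finds two or more independent eQTL signals, each signal
is evaluated separately after conditioning all three traits on the
other index variants. The conditional z-score uses reference LD:
$z_{j|C} = (z_j - r_{jC}R_{CC}^{-1}z_C)/\sqrt{1 - r_{jC}R_{CC}^{-1}r_{Cj}}$,
with a $10^{-6}$ ridge on $R_{CC}$ when its condition number exceeds
$10^8$ and a hard error when the target is nearly collinear with the
condition set (denominator $\le 10^{-6}$). Betas are rebuilt as
$z_{j|C} \cdot se_j$ with the original standard errors retained — a
z-score-scale approximation of the full summary-statistics joint
estimator, which additionally rescales by the residual variance. The
approximation is exact at the level of the z-scores the colocalization
engine consumes. Condition variants absent from a trait's records
(truncated methylation coverage) are dropped from that trait's
condition set.

### Downstream analyses

* **Effect clustering** — MR betas arranged gene-by-trait, each trait
  column z-scored over observed cells (log-odds and per-SD effects are
  not otherwise comparable), missing cells masked and imputed to zero
  after standardization, Euclidean distances, complete-linkage
  agglomeration with id-sorted inputs for deterministic leaf order.
* **Enrichment** — exact hypergeometric upper tail of the overlap
  between a hit list and an annotation set within the universe of
  tested genes. For the "inverse relationship" pattern between trait
  gene-sets the package deliberately exposes only transparent
  sign-concordance counts (`crossTissueCompare()`'s concordance field)
  rather than inventing an unstated statistic.
* **Cross-tissue replication** — effects from a primary tissue are
  looked up in a proxy tissue; replication is proxy $p < 0.05$
  (heuristic, configurable), reported as a percentage with its
  complement and the reverse comparison.
* **Phenome-wide scan** — one gene's instruments against a catalogue
  of outcomes at the Bonferroni threshold $0.05/n_{outcomes}$; the
  pleiotropy count is the number of flagged outcomes.

## The synthetic-data generator

`simulateSummaryStats()` draws marginal z-scores directly:
$z \sim MVN(\sqrt{n}\,R\,\tilde b,\; R)$ over an AR(1) LD backbone
$R_{ij} = \rho^{|i-j|}$, with standardized causal effects $\tilde b$,
$se_j = 1/\sqrt{2\,maf_j(1-maf_j)\,n}$, $\beta_j = z_j se_j$, and
variants on a 1 kb grid. This is exactly the sampling model the ABF
machinery assumes, and it is orders of magnitude faster than
individual-level simulation, which matters because the calibration
suite draws tens of thousands of regions. Binary traits are simulated
on the log-odds scale at the effective sample size
$4/(1/n_{cases}+1/n_{controls})$ — a standard approximation. A
Gaussian-copula haplotype panel (`simulateReferencePanel()`) provides
matching reference genotypes when estimated (rather than true) LD is
wanted.

What the generator does *not* emulate: realistic human LD maps (AR(1)
has no long-range blocks or recombination hotspots), allele-frequency
spectra from demography, imputation error, sample overlap between
exposure and outcome studies, and horizontal pleiotropy. Passing
calibration here therefore shows the estimators are correct *under
their own assumptions*, not that real-data artefacts are handled.

### Calibration choices

The scenario library fixes the study conditions once:

* exposure eQTL at brain scale ($n = 1194$) or blood scale
  ($n = 31684$), GWAS outcomes at $n = 50000$;
* regions of $m = 200$ variants, $\rho = 0.9$;
* standardized causal effects 0.26 (eQTL) and 0.04 (GWAS), i.e.
  expected causal $|z| \approx 9$ for both — strong, unambiguous
  signals, as required for a scenario whose purpose is to verify that
  the PPA > 0.8 rule detects true sharing;
* distinct-causal scenarios place the two variants 100 grid steps
  apart ($r^2 \approx 10^{-9}$);
* the mediation scenario uses the blood-scale exposure with
  standardized effect 0.5 and causal ratio $\theta = 0.3$. The choice
  of a large exposure study is deliberate: the first-order Wald
  interval ignores instrument noise, whose relative contribution to
  the ratio variance is $\theta^2 n_{out}/n_{exp}$ ($\approx 0.14$
  here, predicted coverage $\approx 0.93$). A brain-scale exposure
  ($n = 1194$) would inflate the ratio variance nearly fivefold and
  no first-order interval could be expected to cover at its nominal
  level; that regime calls for `secondOrder = TRUE`.
* truncated methylation coverage mimics restricted QTL release
  formats (probe-window and p-value filters).

Problem sizes used by the test-suite and the acceptance script —
200 replicates for pairwise colocalization rates, 100 for three-way,
200 for mediation recovery and 1000 for interval coverage, 1000
replicates of a 10-gene null study for the family-wise error — were
fixed alongside the scenarios as the smallest sizes at which the
Monte-Carlo error is well below the decision margins being verified.

## Numerical and degenerate-input conventions

* p-values are computed in log space (`twoSidedP()`) and floored at
  the smallest positive normalized double; an exact zero is never
  produced. Downstream computation treats $\beta$ and $se$, not p, as
  authoritative.
* coordinates are 1-based and inclusive everywhere; the cis flank and
  the CpG window include both endpoints.
* a single shared variant forces $PP_{H3} = 0$ exactly (no second
  variant exists); configurations requiring more distinct variants
  than are available get likelihood zero the same way.
* monomorphic panel variants are excluded from LD with a warning;
  constant effect-matrix columns standardize to zero with a warning;
  an empty clump result is a value, not an error, while an empty
  variant intersection is always an error.
* records failing internal consistency (se $\le 0$, identical
  alleles, p inconsistent with $\beta/se$ beyond 10% relative) are
  dropped at load time and counted in the load report.

## Limitations

Reverse causation from outcome to methylation/expression is outside
the model; colocalization at a conditionally independent locus is
necessary, not sufficient, for causality; co-regulated neighbouring
genes can share instruments and cannot be separated by these methods;
and the IVW assumes post-clumping instruments are uncorrelated
($r^2 < 0.01$ residual LD is ignored). MR-Egger and other
pleiotropy-robust estimators are deliberately out of scope.
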