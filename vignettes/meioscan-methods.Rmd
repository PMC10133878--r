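---
title: "meioscan: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{meioscan: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioscan)
```

meioscan implements the computational chain used to nominate a recessive
causal variant for severe male-factor infertility from a small
consanguineous-family exome design, and to characterize the variant's
meiotic consequences: a segregation/frequency/impact filtering cascade with
testis-specificity ranking, single-cell stage profiling, sperm and embryo
FISH aneuploidy statistics, RFLP verification-assay design, and cohort
summaries. Because the raw patient data behind such a study are not
publishable, the package ships a synthetic-data generator that emulates
every input class with known ground truth, so the whole chain is testable
offline by parameter recovery.

This vignette records the statistical models, the conventions adopted where
the methodology leaves room, and the reasoning behind the defaults.

## The filtering cascade

A candidate variant for a recessive condition in a consanguineous family
with two affected brothers, one fertile brother and a fertile control cohort
must satisfy, in order:

1. **Segregation.** Autosomal-recessive: both affected members homozygous
   for the alternate allele; no unaffected family member and no control
   homozygous-alt. X-linked: affected males hemizygous-alt; no unaffected
   male (family or control) hemizygous-alt; carrier mothers permitted. In
   `mode = "both"` the two branches are applied to autosomal and X variants
   respectively and their survivors pooled.
2. **Frequency.** Population MAF strictly below 1% (configurable).
3. **Impact.** Predicted loss of function (stop gained, frameshift, splice)
   unconditionally, or missense at/above a conservation cutoff.

Survivors are ranked by the testis-specificity coefficient of their gene
(below), with ties broken by consequence severity (stop gained > frameshift
> splice > missense) and then genomic position.

Conventions where the procedure is underdetermined, each chosen once and
fixed:

* **Missing MAF is rare.** A variant absent from population databases is
  exactly the kind of novel allele the design targets; it is retained (the
  frequency filter treats `NA` as passing).
* **Missing genotypes.** A missing call in an *affected* member drops the
  variant (the homozygosity evidence cannot be established); a missing call
  in a control drops only that control from that variant's evaluation.
* **Controls exclude only the causative genotype.** Fertile controls may be
  carriers of a recessive allele, so heterozygous controls never exclude a
  variant; only hom-alt (or hemi-alt on X) does.
* **Conservation cutoff defaults to 0** (all missense pass). No numeric
  cutoff is inherent to the method; a missing conservation score counts
  as 0, so unscored missense survives only under the default cutoff.
* A male diploid genotype code on the X chromosome is treated as a hard
  encoding error rather than silently reinterpreted.

## Testis specificity

A gene's specificity for the target tissue is the Pearson product-moment
correlation $r$ between its cross-tissue TPM vector and an
exclusive-expression indicator (1 at the target tissue, 0 elsewhere).
Values near 1 indicate near-exclusive expression. Since Pearson correlation
is invariant under positive affine maps, the indicator's magnitude is
immaterial, and any gene whose profile is a positive-slope affine transform
of the indicator scores exactly 1. TPM values are correlated untransformed
(no log), and genes with zero variance across tissues (silent or perfectly
flat) have no defined correlation: they are flagged undefined and ranked
last rather than assigned an arbitrary score.

## Single-cell stage profiling

* **CPM normalization** rescales each cell to one million total counts;
  cells with zero totals are an error, not silently dropped.
* **Marker verification** clusters cells hierarchically on the marker-gene
  submatrix with distance $1 - r$ (Pearson) and **average linkage**, cuts at
  k = number of annotated types, and reports the adjusted Rand index against
  the annotation plus each marker's own-type versus other-type mean. The
  linkage choice follows common practice for correlation-based expression
  clustering; the method specification names only the Pearson distance.
* **Median-normalized average** follows the 10x Loupe browser convention:
  each cell's counts are rescaled so its total equals the *median* of all
  cell totals, then the gene's rescaled values are averaged within each
  cluster, reported in chronological stage order. With equal library sizes
  this reduces to the plain per-cluster mean. No log transform is applied
  before averaging. The Loupe-internal "significantly expressed genes"
  screen and its p-values are out of scope; profiles are computed for the
  genes the user requests, and cluster-to-stage ordering is taken from the
  annotation, never inferred.
* A profile whose maximum is less than 1.5 times its mean is flagged
  non-informative rather than assigned a peak stage of record.

## FISH ploidy classification

Sperm cells (expected ploidy 1) are classified from per-probe signal
counts; only cells with observable tails enter the tally. The category
rules, in precedence order:

1. **diploid** — every autosomal probe at 2 signals and, when sex probes are
   present, either both at 2 or a total of 2 (XX, YY or XY patterns); this
   covers whole-genome doubling regardless of the doubled cell's sex
   content.
2. **xy_disomy** — at least one X and one Y signal (both sex chromosomes
   retained, the meiosis-I nondisjunction signature). This takes precedence
   over per-chromosome disomy labels.
3. **normal** — every autosome at 1 and exactly one sex signal.
4. **sex_nullisomy** — no sex signal with normal autosomes.
5. **disomy/nullisomy of a single chromosome** — exactly one deviating
   probe at 2 or 0.
6. **complex** — anything else.

Blastomeres (expected ploidy 2) are normal at all-2, with single-probe
deviations labelled trisomy (3), monosomy (1) or nullisomy (0), and
everything else complex.

Summary statistics: the normal-ploidy fraction counts diploid cells as
abnormal (they are abnormal findings, not normal haploids); the share of
aneuploid cells carrying both sex chromosomes is reported only when the
panel probes X and Y and at least one aneuploid cell exists, and flagged
undefined otherwise — for an autosome-only panel the statistic is
unavailable by construction. Case-control comparison of normal/aneuploid
counts uses the two-sided Fisher exact test (point-probability method, via
`stats::fisher.test`); the per-cell classification itself is deterministic
and invariant to probe order.

## Verification assays

* **Digestion.** Recognition sites are IUPAC-expanded (input sequences must
  be unambiguous); non-palindromic sites are additionally searched as their
  reverse complement, cutting on the top strand at the mirrored offset.
  Fragment lengths are top-strand cut to cut and always sum to the sequence
  length; digestion is assumed complete. For non-palindromic sites,
  digesting the reverse complement yields exactly the reversed fragment
  list; for palindromic sites with asymmetric (staggered) cut offsets the
  top-strand convention makes the two directions differ by the overhang
  length — the standard behaviour of single-strand coordinate digest tools.
* **Allele discrimination** digests both allelic sequences and compares the
  fragment-length multisets.
* **Mismatch design** searches exhaustively over single-base substitutions
  within a primer-sized window next to the variant (the variant base itself
  excluded), reporting substitutions that create a recognition site
  overlapping the variant in exactly one allele, ordered deterministically
  by (enzyme, position, base). Multi-base mismatches and primer
  thermodynamics are out of scope.
* **Coding changes** are annotated with 1-based HGVS-style coordinates
  (`c.448C>T`, `p.R150X`), the standard genetic code, and the stop-codon
  class (amber TAG, ochre TAA, opal TGA).
* **Microsatellite haplotype comparison** treats allele-length pairs as
  unordered, compares only markers genotyped in both individuals, and calls
  the backgrounds shared only when every compared marker matches. The
  default panel layout places eight markers within 2 Mb upstream and four
  within 0.7 Mb downstream of the gene.

## Cohort statistics

ICSI fertilization rates are reported as whole percentages rounded half-up
(21/31 prints as 68%), with the raw fraction retained. Carrier-screen
tallies count carriers (het), positives (hom-alt) and mutant alleles
(het = 1, hom-alt = 2) per ethnic group and fertility status, with marginal
totals recomputed and checked against the sum of their parts on every call.
The OAT semen class pools OAT, severe OAT and cryptozoospermia, matching
common screen reporting. Fertility trials are compared on means (mean ±
SEM, SEM = sd/√n with the n−1 sd) with percent reduction relative to the
reference mean and a two-tailed pooled-variance Student t test — the
classical analysis for balanced vial designs; Welch correction is not
applied.

## The synthetic study and its parameters

The generator's defaults encode the emulated study design; all are fixed in
`sim_config()` and none is inferred from data.

| parameter | default | rationale |
|---|---|---|
| family design | 2 affected + 1 fertile brother + parents | the sequenced pedigree |
| controls | 25 fertile males | joint-called control cohort size |
| background variants | 5,000 | exome scale at desk-test runtimes |
| MAF spectrum | Beta(0.5, 10) | rare-skewed site-frequency shape |
| inbreeding F | 1/16 | first-cousin consanguinity |
| planted variant | stop-gained, MAF 1e-4, testis-exclusive gene | the causal-allele profile the cascade targets |
| consequence mix | 40% synonymous, 45% missense, 5% LoF, 10% other | recorded, deliberately simple |
| p(aneuploid sperm) | 0.883 | patient-scale aneuploidy burden |
| p(XY \| aneuploid) | 0.38 | sex-chromosome nondisjunction share |
| FISH cells | 500 | within the 68–521 cells/experiment range |
| scRNA design | 10 clusters × 100 cells | a 13,000-cell atlas scaled down |
| marker blocks | 8 genes/type, baseline mean 20, NB size 20 | well-detected marker panels; supports exact type recovery at a 2-fold effect |
| library sizes | log-normal, sdlog 0.3 | typical depth variation |
| fertility means | wild type 100, mutant 70, 10 vials | a 30% fecundity reduction at the published vial count |

Background genotypes are drawn per sample from Hardy–Weinberg proportions
with the inbreeding adjustment $P(\text{hom-alt}) = Fq + (1-F)q^2$ for
family members and plain HWE for controls; the planted variant is the only
row with enforced Mendelian structure (parents het, affected hom-alt,
fertile brother het or hom-ref at the 2:1 ratio expected among unaffected
offspring of two carriers, controls never hom-alt). Aneuploid FISH cells
draw an error type: XY disomy with the configured probability, otherwise
single-chromosome disomy, nullisomy or whole-cell diploidy (2 signals on
every probe) at 0.4/0.4/0.2. Every generator consumes a single seeded RNG
stream per call, so equal configurations reproduce byte-identical outputs.

What the generator does **not** emulate: linkage disequilibrium and shared
haplotypes (genotypes are independent across variants), sequencing error
and coverage models, compound heterozygosity, realistic transcript
structure, cell-type doublets or ambient RNA, and FISH hybridization
failure. Passing parameter-recovery tests therefore demonstrates the
correctness of the inference chain under its stated model, not robustness
to those real-data artifacts.

## Numerical and testing choices

Rate-recovery checks use the Wilson score interval at 95%, which behaves
sensibly at boundary estimates (0 or 1 observed). Filter outputs are
validated against brute-force row-by-row predicate evaluation on
1,000-variant tables; Fisher p-values against full hypergeometric
enumeration; the specificity score against the textbook Pearson formula;
and digestion against manual scans plus a 1,000-sequence fuzz of the
length-conservation invariant. The end-to-end recovery condition — the
planted variant ranked first in at least 95 of 100 replicate synthetic
exomes at 5,000 variants and 25 controls — runs in about half a minute;
the t-test size check uses 2,000 null replicates. These problem sizes were
chosen as the package's own desk-scale defaults; all are parameters, not
limits.

Known limitations worth restating: the prioritization cascade assumes full
penetrance and a single causal locus; by-chance survivors of all filters
are possible (and tolerated — ranking, not the filters, resolves them);
patient-level published percentages (normal-ploidy rates, survivor counts)
depend on unpublished raw data and are validated here only as recoverable
statistics on synthetic populations with known truth.
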