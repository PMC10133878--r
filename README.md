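# meioscan

Pedigree-aware variant prioritization and meiotic phenotype statistics.

Severe male-factor infertility with repeated IVF failure can be caused by a
single recessive loss-of-function allele in a meiosis gene, producing sperm
with extensive aneuploidy. Identifying such an allele from a small
consanguineous family requires a chain of computations: exome-wide
segregation filtering against the pedigree and a fertile control cohort,
rarity and functional-impact filtering, ranking by testis-specific
expression, single-cell confirmation of meiotic stage expression, FISH-based
aneuploidy quantification in sperm and embryos, and design of the RFLP
assays used to verify and screen the variant. meioscan implements that
chain as a tested, reusable R package for clinical genetics and
reproductive-biology researchers, together with a synthetic-data generator
that plants a known causal variant so every stage can be validated by
parameter recovery — no patient data required.

## The core computations

* **Filtering cascade** (`prioritize_pipeline()`): retain variants with
  genotype pattern *affected* = hom-alt, *unaffected family* ≠ hom-alt,
  *controls* ≠ hom-alt (autosomal-recessive), or the hemizygous analogue on
  X; then MAF < 1%; then LoF or conserved missense. Survivors are ranked by
  testis specificity.
* **Testis specificity** (`specificity_scores()`): for each gene, the
  Pearson correlation *r* between its cross-tissue TPM vector and the
  exclusive-expression indicator **e**(testis) — *r* → 1 means
  testis-exclusive expression.
* **Single-cell profiling** (`cpm_normalize()`, `marker_cluster_verify()`,
  `stage_profile_report()`): CPM normalization, marker-gene hierarchical
  clustering (1 − *r* distance, average linkage, adjusted Rand index
  against the annotation), and per-cluster median-normalized average
  expression across spermatogenesis stages.
* **FISH aneuploidy** (`classify_sperm_cell()`, `classify_blastomere()`,
  `summarize_fish()`): rule-based ploidy calls per cell (normal, disomy,
  nullisomy, XY disomy, diploid, complex; trisomy/monosomy for
  blastomeres), population summaries, and a two-sided Fisher exact
  case-control comparison.
* **Assay design** (`digest()`, `allele_discrimination()`,
  `design_mismatch_site()`, `annotate_cds_substitution()`,
  `compare_flanking_haplotypes()`): in-silico restriction digestion with
  IUPAC sites, allele discrimination, mismatch-primer site creation, coding
  consequence annotation (e.g. `c.448C>T` → `p.R150X`, opal stop), and
  microsatellite flanking-haplotype comparison.
* **Cohort statistics** (`fertilization_rate()`, `tally_screen()`,
  `fertility_compare()`): ICSI fertilization rates, carrier-screen tallies
  with allele counts, and mean ± SEM fertility comparisons with a pooled
  two-tailed Student t test.
* **Synthetic data** (`sim_config()`, `gen_family_exome()`,
  `gen_tissue_matrix()`, `gen_scrna()`, `gen_fish_cells()`,
  `gen_fertility()`): seeded generators for every input class, with ground
  truth retained.

## Worked example

Simulate a complete synthetic study and run the full chain:

```r
library(meioscan)
run <- run_meioscan(sim_config(seed = 11, n_variants = 2000))
print(run)
#> meioscan run (seed 11)
#>   filter cascade: input=2001 -> segregation=1 -> frequency=1 -> impact=1
#>   planted variant 14:23749233:C:T ranked 1
#>   scRNA marker-cluster ARI: 1
#>   RNF212B peak stage: pre-leptotene-zygotene
#>   RNF212B_PARALOG peak stage: diff spermatogonia
#>   FISH normal-ploidy fraction: 0.112 (Fisher p vs control = < 2.22e-16)
#>   fertility mutant: 25.4% reduction, p = 5.9406e-05
```

Reading the output: of 2,001 variants (2,000 background plus the planted
stop-gained allele), exactly one survives segregation, rarity and impact
filtering, and it is the planted variant, ranked first by testis
specificity (*r* = 1). The single-cell annotation is perfectly recovered by
marker clustering (ARI = 1) and the planted gene's expression peaks in the
pre-leptotene–zygotene meiotic stage, unlike its broadly expressed paralog.
The simulated patient's sperm show 11.2% normal ploidy — far below the
~98.7% control baseline (Fisher p < 2.2e-16) — and the simulated mutant
flies show a significant fecundity reduction. A small worked assay
computation:

```r
annotate_cds_substitution(cds, 448, "C", "T")  # cds has codon 150 = CGA
#> c.448: CGA -> TGA (codon 150), p.R150X [stop_gained, opal stop]
fertilization_rate(21, 31)$percent
#> [1] 68
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/meioscan.R` (subcommands `simulate`, `run`, `prioritize`).

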