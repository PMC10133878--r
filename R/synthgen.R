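#' Simulation configuration for the synthetic study
#'
#' Bundles every tunable of the synthetic-data generators. Defaults encode the
#' study design the pipeline is meant to recover: a consanguineous nuclear
#' family (two affected brothers, one fertile brother, both parents) joint
#' called with 25 unrelated fertile control men; ~5,000 exome variants with a
#' Beta(0.5, 10) minor-allele-frequency spectrum; a single planted stop-gained,
#' testis-specific variant at MAF 1e-4; a sperm FISH population with an 88.3%
#' aneuploidy rate of which 38% of errors carry both sex chromosomes; a
#' ten-cluster spermatogenesis single-cell dataset; and vial-level fly
#' fertility assays with a 30% fecundity reduction in the mutant.
#'
#' @param seed integer seed; the same configuration and seed reproduce every
#'   generated dataset byte for byte.
#' @param n_variants number of background exome variants (>= 1).
#' @param n_controls number of unrelated fertile control males.
#' @param maf_shape length-2 positive numeric, Beta shape parameters of the
#'   background MAF distribution.
#' @param inbreeding inbreeding coefficient F in `[0, 1]` applied to family
#'   members' genotype frequencies (default 1/16, first-cousin parents).
#' @param planted list describing the planted causal variant: `gene`, `chrom`,
#'   `consequence` (fixed to `"stop_gained"`), `maf`.
#' @param x_fraction fraction of background variants placed on chromosome X
#'   (males hemizygous).
#' @param maf_missing_rate fraction of background variants with missing MAF
#'   annotation (novel variants).
#' @param geno_missing_rate per-genotype missing-call rate for background
#'   variants (never applied to the planted variant).
#' @param consequence_probs named probabilities for background consequence
#'   categories `synonymous`, `missense`, `lof`, `other`; the LoF mass is split
#'   equally between stop_gained, frameshift and splice.
#' @param p_aneuploid per-sperm-cell probability of aneuploidy.
#' @param p_sexchrom_error probability that an aneuploid cell's error is an XY
#'   disomy (both sex chromosomes retained); ignored for panels without sex
#'   probes.
#' @param n_cells_fish number of sperm cells scored per FISH experiment.
#' @param scrna list of single-cell generator settings: `n_clusters`,
#'   `cells_per_cluster`, `log2_fc` (marker over-expression), `base_mean`
#'   (baseline expected count per gene), `dispersion` (negative-binomial size),
#'   `libsize_sdlog` (log-normal library-size spread), `n_markers_per_cluster`,
#'   `n_background_genes`, `stage_labels` (cluster order along spermatogenesis).
#' @param fertility_means named per-genotype Poisson means for adult progeny
#'   per vial; the first element is the wild-type reference.
#' @param n_vials vials scored per genotype.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_variants = 200)
#' cfg$planted$gene
sim_config <- function(seed = 1L,
                       n_variants = 5000L,
                       n_controls = 25L,
                       maf_shape = c(0.5, 10),
                       inbreeding = 1 / 16,
                       planted = list(gene = "RNF212B", chrom = "14",
                                      consequence = "stop_gained", maf = 1e-4),
                       x_fraction = 0.05,
                       maf_missing_rate = 0.01,
                       geno_missing_rate = 0.002,
                       consequence_probs = c(synonymous = 0.4, missense = 0.45,
                                             lof = 0.05, other = 0.1),
                       p_aneuploid = 0.883,
                       p_sexchrom_error = 0.38,
                       n_cells_fish = 500L,
                       scrna = list(),
                       fertility_means = c(wild_type = 100, mutant = 70),
                       n_vials = 10L) {
  scrna_default <- list(
    n_clusters = 10L, cells_per_cluster = 100L, log2_fc = 2,
    base_mean = 20, dispersion = 20, libsize_sdlog = 0.3,
    n_markers_per_cluster = 8L, n_background_genes = 100L,
    stage_labels = c("undiff spermatogonia", "diff spermatogonia",
                     "pre-leptotene-zygotene", "pachytene",
                     "meiotic division", "early round spermatid",
                     "mid round spermatid", "late round spermatid",
                     "elongating spermatid", "condensed spermatid"))
  scrna <- utils::modifyList(scrna_default, scrna)
  scrna$n_clusters <- as.integer(scrna$n_clusters)
  if (!is.null(scrna$stage_labels) &&
      length(scrna$stage_labels) < scrna$n_clusters) {
    scrna$stage_labels <- paste0("stage_", seq_len(scrna$n_clusters))
  }
  scrna$stage_labels <- scrna$stage_labels[seq_len(scrna$n_clusters)]

  cfg <- list(seed = as.integer(seed), n_variants = as.integer(n_variants),
              n_controls = as.integer(n_controls), maf_shape = maf_shape,
              inbreeding = inbreeding, planted = planted,
              x_fraction = x_fraction, maf_missing_rate = maf_missing_rate,
              geno_missing_rate = geno_missing_rate,
              consequence_probs = consequence_probs,
              p_aneuploid = p_aneuploid,
              p_sexchrom_error = p_sexchrom_error,
              n_cells_fish = as.integer(n_cells_fish), scrna = scrna,
              fertility_means = fertility_means,
              n_vials = as.integer(n_vials))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1L, is.finite(cfg$seed))
  if (cfg$n_variants < 1L) stop("n_variants must be >= 1")
  if (cfg$n_controls < 0L) stop("n_controls must be >= 0")
  if (length(cfg$maf_shape) != 2L || any(cfg$maf_shape <= 0))
    stop("maf_shape must be two positive Beta shape parameters")
  probs <- c(cfg$inbreeding, cfg$x_fraction, cfg$maf_missing_rate,
             cfg$geno_missing_rate, cfg$p_aneuploid, cfg$p_sexchrom_error)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$consequence_probs) - 1) > 1e-8)
    stop("consequence_probs must sum to 1")
  if (!identical(cfg$planted$consequence, "stop_gained"))
    stop("the planted variant must be stop_gained")
  if (cfg$planted$maf < 0 || cfg$planted$maf > 1)
    stop("planted maf must lie in [0, 1]")
  if (any(cfg$fertility_means <= 0)) stop("fertility means must be positive")
  if (cfg$n_vials < 2L) stop("n_vials must be >= 2")
  with(cfg$scrna, {
    if (n_clusters < 1L || cells_per_cluster < 1L) stop("scrna counts must be positive")
    if (base_mean <= 0 || dispersion <= 0 || libsize_sdlog < 0)
      stop("scrna distribution parameters invalid")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration (seed ", x$seed, ")\n", sep = "")
  cat("  exome: ", x$n_variants, " variants, ", x$n_controls,
      " controls, F = ", signif(x$inbreeding, 3), "\n", sep = "")
  cat("  planted: ", x$planted$gene, " ", x$planted$consequence,
      " (MAF ", x$planted$maf, ") on chr", x$planted$chrom, "\n", sep = "")
  cat("  FISH: ", x$n_cells_fish, " cells, p_aneuploid = ", x$p_aneuploid,
      ", p(XY | aneuploid) = ", x$p_sexchrom_error, "\n", sep = "")
  cat("  scRNA: ", x$scrna$n_clusters, " clusters x ",
      x$scrna$cells_per_cluster, " cells, log2FC = ", x$scrna$log2_fc,
      "\n", sep = "")
  cat("  fertility: ", paste(names(x$fertility_means), x$fertility_means,
                             sep = "=", collapse = ", "),
      " (", x$n_vials, " vials each)\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Pedigree and variant containers

#' Construct a pedigree with an unrelated control cohort
#'
#' @param members data.frame with columns `id`, `sex` ("male"/"female"),
#'   `affected` ("yes"/"no"/"unknown"), `father`, `mother` (NA when unknown).
#' @param controls character vector of unrelated fertile control sample ids.
#' @return object of class `pedigree`.
#' @export
pedigree <- function(members, controls = character()) {
  stopifnot(is.data.frame(members),
            all(c("id", "sex", "affected") %in% names(members)))
  if (is.null(members$father)) members$father <- NA_character_
  if (is.null(members$mother)) members$mother <- NA_character_
  ids <- c(members$id, controls)
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  if (!all(members$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (!all(members$affected %in% c("yes", "no", "unknown")))
    stop("affected must be 'yes', 'no' or 'unknown'")
  for (p in c(members$father, members$mother)) {
    if (!is.na(p) && !p %in% members$id)
      stop("parent reference does not resolve: ", p)
  }
  if (!any(members$affected == "yes")) stop("pedigree needs >= 1 affected member")
  structure(list(members = members, controls = as.character(controls)),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  aff <- sum(x$members$affected == "yes")
  cat("Pedigree: ", nrow(x$members), " family members (", aff,
      " affected), ", length(x$controls), " unrelated controls\n", sep = "")
  invisible(x)
}

#' All sample ids of a pedigree (family members plus controls)
#' @param ped a [pedigree()].
#' @return character vector.
#' @export
ped_samples <- function(ped) c(ped$members$id, ped$controls)

#' Construct a variant set
#'
#' Couples a per-variant annotation table with a genotype matrix. Genotype
#' states are `"hom-ref"`, `"het"`, `"hom-alt"` on autosomes, `"hemi-ref"`,
#' `"hemi-alt"` for males on chromosome X, and `"missing"`.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `consequence`, `maf`, `conservation`.
#' @param geno character matrix, one row per variant, one column per sample.
#' @return object of class `variant_set`.
#' @export
variant_set <- function(variants, geno) {
  stopifnot(is.data.frame(variants), is.matrix(geno),
            nrow(variants) == nrow(geno))
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "maf",
            "conservation")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants table lacks columns: ",
                         paste(miss, collapse = ", "))
  ok_states <- c("hom-ref", "het", "hom-alt", "hemi-ref", "hemi-alt", "missing")
  if (!all(geno %in% ok_states))
    stop("invalid genotype state(s): ",
         paste(unique(geno[!geno %in% ok_states]), collapse = ", "))
  bad_maf <- !is.na(variants$maf) & (variants$maf < 0 | variants$maf > 1)
  if (any(bad_maf)) stop("maf outside [0, 1]")
  variants$key <- variant_key(variants)
  rownames(geno) <- variants$key
  structure(list(variants = variants, geno = geno), class = "variant_set")
}

variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("Variant set: ", nrow(x$variants), " variants x ", ncol(x$geno),
      " samples\n", sep = "")
  tab <- sort(table(x$variants$consequence), decreasing = TRUE)
  cat("  consequences: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of variants in a variant set
#' @param vs a [variant_set()].
#' @return integer count.
#' @export
n_variants <- function(vs) nrow(vs$variants)

subset_variant_set <- function(vs, keep) {
  variant_set(vs$variants[keep, , drop = FALSE], vs$geno[keep, , drop = FALSE])
}

## ---------------------------------------------------------------------------
## Family exome generator

sample_states <- function(p_mat, states) {
  ## p_mat: n x k row-stochastic matrix; returns character vector length n
  u <- runif(nrow(p_mat))
  cum <- p_mat
  for (j in seq_len(ncol(p_mat))[-1L]) cum[, j] <- cum[, j - 1L] + p_mat[, j]
  idx <- rowSums(u > cum) + 1L
  states[pmin(idx, length(states))]
}

#' Generate a consanguineous family exome with a planted causal variant
#'
#' Emulates the sequenced design: father, mother, two affected sons, one
#' unaffected son, and `n_controls` unrelated fertile males, joint-genotyped
#' over `n_variants` background variants plus exactly one planted variant.
#' Background autosomal genotypes follow Hardy-Weinberg proportions, with the
#' inbreeding adjustment P(hom-alt) = Fq + (1-F)q^2 (and P(het) = (1-F)2pq)
#' for family members; controls follow plain HWE. A fraction `x_fraction` of
#' background variants sit on chromosome X with hemizygous male genotypes.
#' The planted variant is hom-alt in both affected sons, het in both parents,
#' het or hom-ref in the unaffected son (2:1, the Mendelian ratio among
#' unaffected offspring of two carriers), and never hom-alt in controls.
#'
#' @param config a [sim_config()].
#' @return list with elements `pedigree` ([pedigree()]), `variants`
#'   ([variant_set()]) and `planted_key` (the planted variant's key). The
#'   variant set carries attribute `planted_flagged_common = TRUE` when the
#'   planted MAF is at or above the 1% rarity threshold.
#' @export
#' @examples
#' sim <- gen_family_exome(sim_config(seed = 7, n_variants = 100))
#' sim$variants$variants[sim$variants$variants$key == sim$planted_key, ]
gen_family_exome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 101L)

  controls <- sprintf("C%02d", seq_len(config$n_controls))
  members <- data.frame(
    id = c("F", "M", "P1", "P2", "B3"),
    sex = c("male", "female", "male", "male", "male"),
    affected = c("no", "no", "yes", "yes", "no"),
    father = c(NA, NA, "F", "F", "F"),
    mother = c(NA, NA, "M", "M", "M"),
    stringsAsFactors = FALSE)
  ped <- pedigree(members, controls)
  samples <- ped_samples(ped)

  n <- config$n_variants
  maf <- rbeta(n, config$maf_shape[1], config$maf_shape[2])
  on_x <- runif(n) < config$x_fraction
  chrom <- ifelse(on_x, "X", as.character(sample.int(22L, n, replace = TRUE)))
  pos <- sample.int(2.4e8, n, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  cp <- config$consequence_probs
  cons_class <- sample(names(cp), n, replace = TRUE, prob = cp)
  consequence <- ifelse(
    cons_class == "lof",
    sample(c("stop_gained", "frameshift", "splice"), n, replace = TRUE),
    cons_class)
  conservation <- runif(n)
  gene <- sprintf("GENE%05d", seq_len(n))

  q <- maf; p <- 1 - q; Fcoef <- config$inbreeding
  geno <- matrix("hom-ref", nrow = n, ncol = length(samples),
                 dimnames = list(NULL, samples))
  fam_auto <- cbind(Fcoef * p + (1 - Fcoef) * p^2, (1 - Fcoef) * 2 * p * q,
                    Fcoef * q + (1 - Fcoef) * q^2)
  ctl_auto <- cbind(p^2, 2 * p * q, q^2)
  auto_states <- c("hom-ref", "het", "hom-alt")
  hemi_states <- c("hemi-ref", "hemi-alt")
  is_male <- c(members$sex == "male", rep(TRUE, length(controls)))
  names(is_male) <- samples
  for (s in samples) {
    fam <- s %in% members$id
    probs <- if (fam) fam_auto else ctl_auto
    g <- sample_states(probs, auto_states)
    if (is_male[s] && any(on_x)) {
      ## hemizygous on X: allele drawn at frequency q
      g[on_x] <- ifelse(runif(sum(on_x)) < q[on_x], "hemi-alt", "hemi-ref")
    }
    geno[, s] <- g
  }
  if (config$geno_missing_rate > 0) {
    drop <- matrix(runif(length(geno)) < config$geno_missing_rate,
                   nrow = n)
    geno[drop] <- "missing"
  }

  ## planted causal variant: recessive segregation by construction
  pl <- config$planted
  planted_row <- data.frame(
    chrom = pl$chrom, pos = 23749233L, ref = "C", alt = "T", gene = pl$gene,
    consequence = pl$consequence, maf = pl$maf, conservation = 0.99,
    stringsAsFactors = FALSE)
  pg <- setNames(rep("hom-ref", length(samples)), samples)
  pg[c("P1", "P2")] <- "hom-alt"
  pg[c("F", "M")] <- "het"
  pg["B3"] <- sample(c("het", "hom-ref"), 1L, prob = c(2, 1))
  q0 <- pl$maf
  pg[controls] <- ifelse(runif(length(controls)) < 2 * (1 - q0) * q0,
                         "het", "hom-ref")

  variants <- rbind(
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
               consequence = consequence,
               maf = ifelse(runif(n) < config$maf_missing_rate, NA_real_, maf),
               conservation = conservation, stringsAsFactors = FALSE),
    planted_row)
  geno <- rbind(geno, matrix(pg, nrow = 1L, dimnames = list(NULL, samples)))
  ord <- order(variants$chrom, variants$pos)
  vs <- variant_set(variants[ord, , drop = FALSE], geno[ord, , drop = FALSE])
  attr(vs, "planted_flagged_common") <- pl$maf >= 0.01

  list(pedigree = ped, variants = vs, planted_key = variant_key(planted_row))
}

## ---------------------------------------------------------------------------
## Tissue expression generator

#' Generate a cross-tissue TPM matrix with known specificity structure
#'
#' Emulates a GTEx-style genes x tissues median TPM matrix containing three
#' ground-truth classes: testis-exclusive genes (positive TPM only in the
#' target tissue), broadly expressed genes, and silent genes. When `genes` is
#' supplied (e.g. the gene column of a generated exome) the rows are those
#' genes; `force_exclusive` genes are always made testis-exclusive.
#'
#' @param config a [sim_config()].
#' @param n_genes number of genes when `genes` is NULL.
#' @param tissues character vector of >= 2 tissue names; must contain `target`.
#' @param target the designated specific tissue (default `"testis"`).
#' @param genes optional character vector of gene names.
#' @param force_exclusive genes forced into the testis-exclusive class
#'   (defaults to the configured planted gene).
#' @param frac_exclusive,frac_silent class fractions for the remaining genes.
#' @return numeric matrix (genes x tissues) with attributes `target_tissue`
#'   and `truth` (named class labels).
#' @export
gen_tissue_matrix <- function(config, n_genes = 500L,
                              tissues = c("testis", "ovary", "liver", "brain",
                                          "heart", "lung", "kidney", "spleen",
                                          "muscle", "pancreas", "skin",
                                          "whole_blood"),
                              target = "testis", genes = NULL,
                              force_exclusive = config$planted$gene,
                              frac_exclusive = 0.02, frac_silent = 0.05) {
  validate_sim_config(config)
  if (length(tissues) < 2L) stop("need >= 2 tissues")
  if (!target %in% tissues) stop("target tissue absent from tissue list")
  set.seed(config$seed + 202L)
  if (is.null(genes)) genes <- sprintf("GENE%05d", seq_len(n_genes))
  genes <- unique(c(genes, force_exclusive))
  n <- length(genes)

  truth <- sample(c("testis_exclusive", "broad", "silent"), n, replace = TRUE,
                  prob = c(frac_exclusive, 1 - frac_exclusive - frac_silent,
                           frac_silent))
  names(truth) <- genes
  truth[intersect(force_exclusive, genes)] <- "testis_exclusive"

  mat <- matrix(0, nrow = n, ncol = length(tissues),
                dimnames = list(genes, tissues))
  excl <- truth == "testis_exclusive"
  mat[excl, target] <- rlnorm(sum(excl), meanlog = log(50), sdlog = 0.5)
  broad <- truth == "broad"
  mat[broad, ] <- rlnorm(sum(broad) * length(tissues),
                         meanlog = log(20), sdlog = 1)
  structure(mat, target_tissue = target, truth = truth)
}

## ---------------------------------------------------------------------------
## Single-cell generator

#' Generate a single-cell spermatogenesis count matrix
#'
#' Draws a genes x cells raw count matrix from a negative-binomial hierarchy:
#' each of `n_clusters` cell types (ordered along spermatogenesis) carries a
#' disjoint block of marker genes over-expressed by `2^log2_fc`; per-cell
#' library-size factors are log-normal. A designated target gene (the planted
#' gene by default) is over-expressed in the meiotic clusters, peaking at the
#' pre-leptotene-zygotene stage, and a broad comparison paralog gene is
#' expressed early and uniformly thereafter — emulating the stage profile the
#' pipeline is meant to read out.
#'
#' @param config a [sim_config()]; see the `scrna` element.
#' @return list with `counts` (integer matrix, genes x cells), `annotation`
#'   (data.frame `barcode`, `cluster`, `stage_label`, `stage_index`) and
#'   `markers` (named list cell-type -> marker genes).
#' @export
gen_scrna <- function(config) {
  validate_sim_config(config)
  sc <- config$scrna
  if (sc$n_clusters < 3L) stop("need >= 3 clusters along the stage order")
  set.seed(config$seed + 303L)

  k <- sc$n_clusters
  n_cells <- k * sc$cells_per_cluster
  clusters <- rep(seq_len(k), each = sc$cells_per_cluster)
  barcodes <- sprintf("CELL%05d", seq_len(n_cells))

  markers <- lapply(seq_len(k), function(i)
    sprintf("MARK%02d_%02d", i, seq_len(sc$n_markers_per_cluster)))
  names(markers) <- sc$stage_labels
  target_gene <- config$planted$gene
  paralog_gene <- paste0(target_gene, "_PARALOG")
  genes <- c(unlist(markers), sprintf("BG%04d", seq_len(sc$n_background_genes)),
             target_gene, paralog_gene)

  fc <- 2^sc$log2_fc
  mu <- matrix(sc$base_mean, nrow = length(genes), ncol = k,
               dimnames = list(genes, NULL))
  for (i in seq_len(k)) mu[markers[[i]], i] <- sc$base_mean * fc
  ## target gene: meiotic peak at the pre-leptotene-zygotene cluster (index 3),
  ## elevated through the meiotic division cluster, low elsewhere
  meiotic <- 3:min(5L, k)
  mu[target_gene, ] <- sc$base_mean * 0.2
  mu[target_gene, meiotic] <- sc$base_mean * fc
  mu[target_gene, meiotic[1]] <- sc$base_mean * fc * 2
  ## paralog: early expression, flat and low through meiosis
  mu[paralog_gene, ] <- sc$base_mean * 0.5
  mu[paralog_gene, seq_len(min(2L, k))] <- sc$base_mean * fc

  libfac <- rlnorm(n_cells, meanlog = -sc$libsize_sdlog^2 / 2,
                   sdlog = sc$libsize_sdlog)
  mu_cells <- mu[, clusters, drop = FALSE] *
    rep(libfac, each = length(genes))
  counts <- matrix(rnbinom(length(mu_cells), mu = mu_cells,
                           size = sc$dispersion),
                   nrow = length(genes),
                   dimnames = list(genes, barcodes))

  annotation <- data.frame(
    barcode = barcodes, cluster = clusters,
    stage_label = sc$stage_labels[clusters], stage_index = clusters,
    stringsAsFactors = FALSE)
  list(counts = counts, annotation = annotation, markers = markers,
       target_gene = target_gene, paralog_gene = paralog_gene)
}

## ---------------------------------------------------------------------------
## FISH generator

#' Define a FISH probe panel
#'
#' @param probes chromosome labels, e.g. `c("X", "Y", "18")`.
#' @param expected_ploidy 1 for sperm, 2 for blastomeres.
#' @param sex_probes subset of `probes` targeting the sex chromosomes.
#' @return object of class `fish_panel`.
#' @export
fish_panel <- function(probes, expected_ploidy = 1L,
                       sex_probes = intersect(probes, c("X", "Y"))) {
  probes <- as.character(probes)
  if (anyDuplicated(probes)) stop("probes must be unique")
  if (!length(probes)) stop("panel must contain >= 1 probe")
  if (!all(sex_probes %in% probes)) stop("sex_probes must be a subset of probes")
  if (!expected_ploidy %in% 1:2) stop("expected_ploidy must be 1 or 2")
  structure(list(probes = probes, expected_ploidy = as.integer(expected_ploidy),
                 sex_probes = as.character(sex_probes)),
            class = "fish_panel")
}

#' Generate per-cell FISH signal counts for a sperm population
#'
#' Each cell is a normal haploid with probability `1 - p_aneuploid`; otherwise
#' an error type is drawn: XY disomy with probability `p_sexchrom_error` (when
#' the panel carries both sex probes), else single-chromosome disomy,
#' single-chromosome nullisomy or whole-genome diploidy (2 signals on every
#' probe) with relative weights 0.4 / 0.4 / 0.2.
#'
#' @param config a [sim_config()].
#' @param panel a [fish_panel()] with `expected_ploidy = 1`.
#' @param n_cells number of cells (defaults to `config$n_cells_fish`).
#' @return data.frame: `cell`, one count column per probe, `tail_observed`,
#'   and the ground-truth `truth` category label.
#' @export
gen_fish_cells <- function(config, panel = fish_panel(c("X", "Y", "18")),
                           n_cells = config$n_cells_fish) {
  validate_sim_config(config)
  stopifnot(inherits(panel, "fish_panel"), panel$expected_ploidy == 1L)
  set.seed(config$seed + 404L)

  probes <- panel$probes
  sexp <- panel$sex_probes
  autos <- setdiff(probes, sexp)
  both_sex <- all(c("X", "Y") %in% sexp)

  counts <- matrix(0L, nrow = n_cells, ncol = length(probes),
                   dimnames = list(NULL, probes))
  truth <- character(n_cells)
  aneu <- runif(n_cells) < config$p_aneuploid
  carried <- if (length(sexp))
    sample(sexp, n_cells, replace = TRUE) else rep(NA_character_, n_cells)

  for (i in seq_len(n_cells)) {
    counts[i, autos] <- 1L
    if (length(sexp)) counts[i, carried[i]] <- 1L
    if (!aneu[i]) { truth[i] <- "normal"; next }
    if (both_sex && runif(1) < config$p_sexchrom_error) {
      counts[i, c("X", "Y")] <- 1L
      truth[i] <- "xy_disomy"
      next
    }
    type <- sample(c("disomy", "nullisomy", "diploid"), 1L,
                   prob = c(0.4, 0.4, 0.2))
    if (type == "diploid") {
      counts[i, ] <- 0L
      counts[i, autos] <- 2L
      if (length(sexp)) counts[i, sexp] <- 2L
      truth[i] <- "diploid"
    } else {
      pool <- c(autos, if (length(sexp)) carried[i])
      chr <- sample(pool, 1L)
      if (type == "disomy") {
        counts[i, chr] <- counts[i, chr] + 1L
        truth[i] <- paste0("disomy_", chr)
      } else {
        counts[i, chr] <- 0L
        truth[i] <- if (chr %in% sexp) "sex_nullisomy"
                    else paste0("nullisomy_", chr)
      }
    }
  }
  out <- data.frame(cell = sprintf("SP%05d", seq_len(n_cells)), counts,
                    tail_observed = TRUE, truth = truth,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out
}

## ---------------------------------------------------------------------------
## Fertility generator

#' Generate vial-level fertility trials
#'
#' Per-vial adult progeny counts are Poisson with the configured per-genotype
#' mean; the default design scores 10 vials per genotype, with the first
#' configured genotype as the wild-type reference.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `genotype`, `vial`, `progeny`.
#' @export
gen_fertility <- function(config) {
  validate_sim_config(config)
  if (length(config$fertility_means) < 2L)
    stop("need >= 2 genotypes including a wild-type reference")
  set.seed(config$seed + 505L)
  gts <- names(config$fertility_means)
  do.call(rbind, lapply(gts, function(g) {
    data.frame(genotype = g, vial = seq_len(config$n_vials),
               progeny = rpois(config$n_vials, config$fertility_means[[g]]),
               stringsAsFactors = FALSE)
  }))
}
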