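#' Autosomal-recessive segregation filter
#'
#' Retains variants compatible with a fully penetrant recessive model in the
#' family: every affected member homozygous for the alternate allele, no
#' unaffected family member homozygous-alt, and no control homozygous-alt.
#' A variant with a missing genotype in any affected member is dropped
#' (conservative); a missing genotype in a control drops that control from the
#' evaluation of that variant only. Heterozygous controls are permitted —
#' the fertile control cohort excludes only the causative (hom-alt) genotype.
#'
#' @param vs a [variant_set()] restricted to autosomal (non-hemizygous)
#'   variants; hemizygous rows are ignored by this filter.
#' @param ped a [pedigree()]; every member and control must be genotyped.
#' @return the retained [variant_set()].
#' @export
filter_recessive <- function(vs, ped) {
  check_samples_present(vs, ped)
  g <- vs$geno
  affected <- ped$members$id[ped$members$affected == "yes"]
  unaffected <- ped$members$id[ped$members$affected == "no"]
  controls <- ped$controls

  hemi <- rowSums(matrix(g %in% c("hemi-ref", "hemi-alt"), nrow = nrow(g))) > 0
  aff_ok <- rowSums(g[, affected, drop = FALSE] == "hom-alt") == length(affected)
  unaff_ok <- rowSums(g[, unaffected, drop = FALSE] == "hom-alt") == 0
  ctl_ok <- if (length(controls))
    rowSums(g[, controls, drop = FALSE] == "hom-alt") == 0 else TRUE
  keep <- !hemi & aff_ok & unaff_ok & ctl_ok
  subset_variant_set(vs, keep)
}

#' X-linked recessive segregation filter
#'
#' Operates on chromosome-X variants with hemizygous male genotype encoding:
#' retains variants where every affected male is hemizygous-alt and no
#' unaffected male — in the family or in the control cohort — carries the
#' hemizygous-alt state. Carrier (heterozygous) mothers are permitted.
#'
#' @param vs a [variant_set()] of X-chromosome variants; a male `het` call is
#'   an encoding violation and raises an error.
#' @param ped a [pedigree()]. Controls are assumed male (fertile men).
#' @return the retained [variant_set()].
#' @export
filter_xlinked <- function(vs, ped) {
  check_samples_present(vs, ped)
  g <- vs$geno
  males <- ped$members$id[ped$members$sex == "male"]
  male_cols <- c(males, ped$controls)
  bad <- g[, male_cols, drop = FALSE] %in% c("het", "hom-alt", "hom-ref")
  if (any(bad)) {
    stop("diploid genotype state for male sample(s) on X: ",
         paste(unique(colnames(g[, male_cols, drop = FALSE])[
           which(matrix(bad, nrow = nrow(g)), arr.ind = TRUE)[, 2L]]),
           collapse = ", "))
  }
  aff_m <- intersect(ped$members$id[ped$members$affected == "yes"], males)
  unaff_m <- c(intersect(ped$members$id[ped$members$affected == "no"], males),
               ped$controls)
  aff_ok <- rowSums(g[, aff_m, drop = FALSE] == "hemi-alt") == length(aff_m)
  miss_aff <- rowSums(g[, aff_m, drop = FALSE] == "missing") > 0
  unaff_ok <- rowSums(g[, unaff_m, drop = FALSE] == "hemi-alt") == 0
  subset_variant_set(vs, aff_ok & !miss_aff & unaff_ok)
}

check_samples_present <- function(vs, ped) {
  missing <- setdiff(ped_samples(ped), colnames(vs$geno))
  if (length(missing))
    stop("pedigree sample(s) absent from genotype matrix: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Population-frequency filter
#'
#' Retains variants with minor allele frequency strictly below `threshold`.
#' A missing MAF is treated as rare and retained: novel variants absent from
#' population databases are prime candidates.
#'
#' @param vs a [variant_set()].
#' @param threshold frequency cutoff in (0, 1]; default 0.01 (MAF < 1%).
#' @return the retained [variant_set()].
#' @export
filter_frequency <- function(vs, threshold = 0.01) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  maf <- vs$variants$maf
  subset_variant_set(vs, is.na(maf) | maf < threshold)
}

#' Functional-impact filter
#'
#' Retains predicted loss-of-function variants (stop_gained, frameshift,
#' splice) unconditionally, and missense variants whose conservation score is
#' at or above `conservation_cutoff`. Synonymous and other categories are
#' dropped. A missing conservation score counts as 0, so missense variants
#' without a score pass only under the default cutoff of 0.
#'
#' @param vs a [variant_set()].
#' @param conservation_cutoff minimum conservation for missense (default 0).
#' @return the retained [variant_set()].
#' @export
filter_impact <- function(vs, conservation_cutoff = 0) {
  cons <- vs$variants$conservation
  cons[is.na(cons)] <- 0
  lof <- vs$variants$consequence %in% c("stop_gained", "frameshift", "splice")
  mis <- vs$variants$consequence == "missense" & cons >= conservation_cutoff
  subset_variant_set(vs, lof | mis)
}

severity_rank <- function(consequence) {
  order_tab <- c(stop_gained = 1, frameshift = 2, splice = 3, missense = 4,
                 synonymous = 5, other = 6)
  r <- order_tab[consequence]
  r[is.na(r)] <- 7
  unname(r)
}

#' Rank surviving candidate variants by testis specificity
#'
#' Orders filter survivors by their gene's specificity coefficient r
#' (descending), breaking ties by consequence severity (stop_gained >
#' frameshift > splice > missense) and then by genomic position. A gene absent
#' from the specificity mapping receives the mapping's minimum r and is
#' flagged. Evidence tags (e.g. "meiosis", "spermatogenesis" associations) are
#' attached for reporting but never used for ordering.
#'
#' @param vs a [variant_set()] of filter survivors.
#' @param specificity named numeric vector, gene -> Pearson r.
#' @param evidence named character (or list) of tags per gene, optional.
#' @return a `candidate_report`: data.frame with `rank`, variant columns,
#'   `specificity_r`, `r_imputed` flag and `evidence`.
#' @export
rank_candidates <- function(vs, specificity, evidence = NULL) {
  v <- vs$variants
  if (nrow(v) == 0L) {
    rep0 <- cbind(v[, c("key", "chrom", "pos", "ref", "alt", "gene",
                        "consequence", "maf")],
                  specificity_r = numeric(0), r_imputed = logical(0),
                  evidence = character(0), rank = integer(0))
    return(structure(rep0, class = c("candidate_report", "data.frame")))
  }
  r <- specificity[v$gene]
  imputed <- is.na(r) | !v$gene %in% names(specificity)
  fallback <- if (length(specificity)) min(specificity, na.rm = TRUE) else -1
  r[imputed] <- fallback
  ev <- if (is.null(evidence)) rep("", nrow(v)) else {
    e <- evidence[v$gene]
    vapply(e, function(x) if (is.null(x) || all(is.na(x))) ""
           else paste(x, collapse = ";"), character(1))
  }
  ord <- order(-r, severity_rank(v$consequence), v$chrom, v$pos)
  out <- cbind(v[ord, c("key", "chrom", "pos", "ref", "alt", "gene",
                        "consequence", "maf")],
               specificity_r = unname(r[ord]),
               r_imputed = unname(imputed[ord]),
               evidence = unname(ev[ord]))
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("candidate_report", "data.frame"))
}

#' @export
print.candidate_report <- function(x, n = 10L, ...) {
  cat("Candidate report: ", nrow(x), " variant(s)\n", sep = "")
  counts <- attr(x, "stage_counts")
  if (!is.null(counts))
    cat("  survivors per stage: ",
        paste(names(counts), counts, sep = "=", collapse = " -> "), "\n",
        sep = "")
  if (nrow(x))
    print.data.frame(utils::head(
      x[, c("rank", "gene", "key", "consequence", "specificity_r")], n))
  invisible(x)
}

#' Full candidate-prioritization cascade
#'
#' Composes the segregation filter (autosomal-recessive, X-linked, or the
#' union of both), the population-frequency filter, the functional-impact
#' filter, and specificity ranking, recording the survivor count after each
#' stage. Autosomal and X rows are routed to their respective segregation
#' filters by their genotype encoding.
#'
#' @param vs a [variant_set()].
#' @param ped a [pedigree()].
#' @param specificity named numeric gene -> r (e.g. from
#'   [specificity_scores()]), or a `specificity_result`.
#' @param mode `"recessive"`, `"xlinked"` or `"both"`.
#' @param maf_threshold frequency cutoff (default 0.01).
#' @param conservation_cutoff missense conservation cutoff (default 0).
#' @param evidence optional gene -> tags mapping passed to [rank_candidates()].
#' @return a `candidate_report` with attribute `stage_counts`.
#' @export
#' @examples
#' sim <- gen_family_exome(sim_config(seed = 3, n_variants = 300))
#' expr <- gen_tissue_matrix(sim_config(seed = 3),
#'                           genes = sim$variants$variants$gene)
#' spec <- specificity_scores(expr)
#' rep <- prioritize_pipeline(sim$variants, sim$pedigree, spec)
#' rep$gene[1]
prioritize_pipeline <- function(vs, ped, specificity,
                                mode = c("both", "recessive", "xlinked"),
                                maf_threshold = 0.01,
                                conservation_cutoff = 0,
                                evidence = NULL) {
  mode <- match.arg(mode)
  if (inherits(specificity, "specificity_result"))
    specificity <- setNames(specificity$r, specificity$gene)
  is_x <- vs$variants$chrom %in% c("X", "chrX")
  counts <- c(input = n_variants(vs))

  seg_parts <- list()
  if (mode %in% c("recessive", "both")) {
    auto <- subset_variant_set(vs, !is_x)
    seg_parts$recessive <- filter_recessive(auto, ped)
  }
  if (mode %in% c("xlinked", "both")) {
    xv <- subset_variant_set(vs, is_x)
    seg_parts$xlinked <- filter_xlinked(xv, ped)
  }
  seg <- if (length(seg_parts) == 1L) seg_parts[[1L]] else
    variant_set(do.call(rbind, lapply(seg_parts, function(p) p$variants)),
                do.call(rbind, lapply(seg_parts, function(p) p$geno)))
  counts <- c(counts, segregation = n_variants(seg))

  freq <- filter_frequency(seg, maf_threshold)
  counts <- c(counts, frequency = n_variants(freq))
  imp <- filter_impact(freq, conservation_cutoff)
  counts <- c(counts, impact = n_variants(imp))

  report <- rank_candidates(imp, specificity, evidence)
  attr(report, "stage_counts") <- counts
  report
}
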