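# Shared fixtures and independent oracles, built in code at test time.

## Minimal family: father, mother, two affected sons, one fertile son,
## plus a configurable control cohort.
tiny_pedigree <- function(n_controls = 3L) {
  members <- data.frame(
    id = c("F", "M", "P1", "P2", "B3"),
    sex = c("male", "female", "male", "male", "male"),
    affected = c("no", "no", "yes", "yes", "no"),
    father = c(NA, NA, "F", "F", "F"),
    mother = c(NA, NA, "M", "M", "M"),
    stringsAsFactors = FALSE)
  pedigree(members, sprintf("C%02d", seq_len(n_controls)))
}

## Variant set from a genotype matrix (rows: variants, cols: samples) and
## optional annotation overrides.
make_vs <- function(geno, chrom = "1", consequence = "missense",
                    maf = 0.001, conservation = 0.5, gene = NULL) {
  n <- nrow(geno)
  if (is.null(gene)) gene <- sprintf("G%03d", seq_len(n))
  variants <- data.frame(
    chrom = rep_len(chrom, n), pos = seq_len(n) * 100L,
    ref = "A", alt = "G", gene = gene,
    consequence = rep_len(consequence, n),
    maf = rep_len(maf, n), conservation = rep_len(conservation, n),
    stringsAsFactors = FALSE)
  variant_set(variants, geno)
}

## Random autosomal genotype matrix over the pedigree's samples.
random_auto_geno <- function(n, ped, p_missing = 0.05) {
  samples <- ped_samples(ped)
  states <- c("hom-ref", "het", "hom-alt", "missing")
  matrix(sample(states, n * length(samples), replace = TRUE,
                prob = c(0.6, 0.2, 0.2 - p_missing, p_missing)),
         nrow = n, dimnames = list(NULL, samples))
}

## Random X genotype matrix: males hemizygous, females diploid.
random_x_geno <- function(n, ped, p_missing = 0.05) {
  samples <- ped_samples(ped)
  male <- c(setNames(ped$members$sex == "male", ped$members$id),
            setNames(rep(TRUE, length(ped$controls)), ped$controls))
  g <- matrix(NA_character_, nrow = n, ncol = length(samples),
              dimnames = list(NULL, samples))
  for (s in samples) {
    g[, s] <- if (male[s])
      sample(c("hemi-ref", "hemi-alt", "missing"), n, replace = TRUE,
             prob = c(0.6, 0.4 - p_missing, p_missing))
    else
      sample(c("hom-ref", "het", "hom-alt", "missing"), n, replace = TRUE,
             prob = c(0.5, 0.3, 0.2 - p_missing, p_missing))
  }
  g
}

## Brute-force row-by-row segregation predicates (independent oracles).
oracle_recessive <- function(geno, ped) {
  aff <- ped$members$id[ped$members$affected == "yes"]
  unaff <- ped$members$id[ped$members$affected == "no"]
  ctl <- ped$controls
  vapply(seq_len(nrow(geno)), function(i) {
    g <- geno[i, ]
    all(g[aff] == "hom-alt") &&
      !any(g[unaff] == "hom-alt") &&
      !any(g[ctl] == "hom-alt")
  }, logical(1))
}

oracle_xlinked <- function(geno, ped) {
  males <- ped$members$id[ped$members$sex == "male"]
  aff_m <- intersect(ped$members$id[ped$members$affected == "yes"], males)
  unaff_m <- c(intersect(ped$members$id[ped$members$affected == "no"], males),
               ped$controls)
  vapply(seq_len(nrow(geno)), function(i) {
    g <- geno[i, ]
    all(g[aff_m] == "hemi-alt") && !any(g[unaff_m] == "hemi-alt")
  }, logical(1))
}

## Hand-rolled Pearson correlation (textbook formula).
oracle_pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

## Two-sided Fisher exact p for a 2x2 table by full hypergeometric
## enumeration (point-probability method).
oracle_fisher_2x2 <- function(tab) {
  m <- tab[1, 1] + tab[2, 1]   # first-column margin
  n <- tab[1, 2] + tab[2, 2]
  k <- tab[1, 1] + tab[1, 2]   # first-row margin
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Table 2 of the screen, reconstructed as an individual-level cohort:
## infertile TBGS 57 (22 OAT-group, 35 AZO), other Jews 255 (176/79, one
## hom-alt positive among the OAT-group), non-Jews 26 (23/3); fertile TBGS
## 21, other Jews 164 (85 normozoospermic overall among fertile, the rest
## untested).
make_screen_cohort <- function() {
  mk <- function(group, status, classes, genotypes) {
    data.frame(group = group, status = status, semen_class = classes,
               genotype = genotypes, stringsAsFactors = FALSE)
  }
  inf <- rbind(
    mk("TBGS", "infertile", rep(c("OAT-group", "AZO"), c(22, 35)), "hom-ref"),
    mk("OtherJews", "infertile", rep(c("OAT-group", "AZO"), c(176, 79)),
       c("hom-alt", rep("hom-ref", 254))),
    mk("nonJews", "infertile", rep(c("OAT-group", "AZO"), c(23, 3)), "hom-ref"))
  fert <- rbind(
    mk("TBGS", "fertile", rep(c("normozoospermic", "untested"), c(10, 11)),
       "hom-ref"),
    mk("OtherJews", "fertile",
       rep(c("normozoospermic", "untested"), c(75, 89)), "hom-ref"))
  cohort <- rbind(inf, fert)
  cohort$id <- sprintf("IND%03d", seq_len(nrow(cohort)))
  cohort
}
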