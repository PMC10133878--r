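test_that("recessive filter retains the canonical planted pattern and drops violations", {
  ped <- tiny_pedigree(3)
  base <- setNames(rep("hom-ref", 8), ped_samples(ped))
  planted <- base
  planted[c("P1", "P2")] <- "hom-alt"; planted[c("F", "M")] <- "het"
  planted["B3"] <- "het"
  sib_homalt <- planted; sib_homalt["B3"] <- "hom-alt"
  ctl_homalt <- planted; ctl_homalt["C01"] <- "hom-alt"
  ctl_het <- planted; ctl_het["C02"] <- "het"
  aff_missing <- planted; aff_missing["P1"] <- "missing"
  aff_het <- planted; aff_het["P2"] <- "het"

  g <- rbind(planted, sib_homalt, ctl_homalt, ctl_het, aff_missing, aff_het)
  vs <- make_vs(g)
  kept <- filter_recessive(vs, ped)$variants$pos / 100
  expect_setequal(kept, c(1, 4))  # planted pattern; het controls tolerated
})

test_that("recessive filter errors when a pedigree sample is ungenotyped", {
  ped <- tiny_pedigree(2)
  g <- matrix("hom-ref", nrow = 2, ncol = 6,
              dimnames = list(NULL, setdiff(ped_samples(ped), "P2")))
  expect_error(filter_recessive(make_vs(g), ped), "P2")
})

test_that("recessive filter equals brute-force predicate evaluation", {
  set.seed(101)
  ped <- tiny_pedigree(5)
  g <- random_auto_geno(1000, ped)
  vs <- make_vs(g)
  got <- filter_recessive(vs, ped)$variants$key
  want <- vs$variants$key[oracle_recessive(g, ped)]
  expect_identical(got, want)
})

test_that("X-linked filter handles hemizygous patterns and equals its oracle", {
  ped <- tiny_pedigree(4)
  base <- setNames(rep("hemi-ref", 9), ped_samples(ped))
  base["M"] <- "hom-ref"
  canonical <- base
  canonical[c("P1", "P2")] <- "hemi-alt"; canonical["M"] <- "het"
  ctl_hemialt <- canonical; ctl_hemialt["C03"] <- "hemi-alt"
  sib_hemialt <- canonical; sib_hemialt["B3"] <- "hemi-alt"
  g <- rbind(canonical, ctl_hemialt, sib_hemialt)
  vs <- make_vs(g, chrom = "X")
  expect_identical(filter_xlinked(vs, ped)$variants$pos, 100L)

  ## diploid male encoding on X is a hard error
  bad <- canonical; bad["P1"] <- "het"
  expect_error(filter_xlinked(make_vs(rbind(bad), chrom = "X"), ped), "male")

  set.seed(202)
  gx <- random_x_geno(1000, ped)
  vsx <- make_vs(gx, chrom = "X")
  got <- filter_xlinked(vsx, ped)$variants$key
  want <- vsx$variants$key[oracle_xlinked(gx, ped)]
  expect_identical(got, want)
})

test_that("frequency filter is strict at the threshold and keeps missing MAF", {
  ped <- tiny_pedigree(1)
  g <- matrix("hom-ref", nrow = 3, ncol = 6,
              dimnames = list(NULL, ped_samples(ped)))
  vs <- make_vs(g, maf = c(0.0001, 0.01, NA))
  kept <- filter_frequency(vs)$variants$maf
  expect_equal(sort(kept, na.last = TRUE), c(0.0001, NA))
  expect_error(filter_frequency(vs, threshold = 0), "threshold")
  expect_error(filter_frequency(vs, threshold = 1.5), "threshold")
})

test_that("impact filter keeps LoF always and missense at/above the cutoff", {
  ped <- tiny_pedigree(1)
  g <- matrix("hom-ref", nrow = 5, ncol = 6,
              dimnames = list(NULL, ped_samples(ped)))
  vs <- make_vs(g,
                consequence = c("stop_gained", "synonymous", "missense",
                                "missense", "other"),
                conservation = c(0, 0.9, 0.5, 0.49, 0.9))
  kept <- filter_impact(vs, conservation_cutoff = 0.5)$variants$consequence
  expect_identical(kept, c("stop_gained", "missense"))
  ## boundary: conservation exactly at the cutoff passes
  expect_true(300L %in% filter_impact(vs, 0.5)$variants$pos)
})

test_that("ranking orders by specificity with severity and position tie-breaks", {
  ped <- tiny_pedigree(1)
  g <- matrix("hom-alt", nrow = 2, ncol = 6,
              dimnames = list(NULL, ped_samples(ped)))
  vs <- make_vs(g, consequence = c("missense", "stop_gained"),
                gene = c("BROAD", "TSPEC"))
  rep1 <- rank_candidates(vs, c(TSPEC = 0.95, BROAD = 0.10))
  expect_identical(rep1$gene, c("TSPEC", "BROAD"))
  expect_identical(rep1$rank, 1:2)

  ## equal r: stop_gained outranks missense
  rep2 <- rank_candidates(vs, c(TSPEC = 0.5, BROAD = 0.5))
  expect_identical(rep2$consequence[1], "stop_gained")

  ## single survivor is rank 1 regardless of r
  single <- subset_vs <- make_vs(g[1, , drop = FALSE], gene = "LONE")
  rep3 <- rank_candidates(single, c(OTHER = 0.99))
  expect_identical(rep3$rank, 1L)
  expect_true(rep3$r_imputed[1])
  expect_equal(rep3$specificity_r[1], 0.99)  # the mapping minimum, flagged
})

test_that("frequency and impact filters commute", {
  set.seed(77)
  ped <- tiny_pedigree(2)
  g <- random_auto_geno(300, ped)
  vs <- make_vs(g,
                consequence = sample(c("stop_gained", "missense", "synonymous",
                                       "other"), 300, replace = TRUE),
                maf = ifelse(runif(300) < 0.1, NA, runif(300, 0, 0.05)),
                conservation = runif(300))
  a <- filter_impact(filter_frequency(vs), 0.3)$variants$key
  b <- filter_frequency(filter_impact(vs, 0.3))$variants$key
  expect_identical(a, b)
})

test_that("full cascade recovers the planted variant with non-increasing stage counts", {
  cfg <- sim_config(seed = 17, n_variants = 2000)
  sim <- gen_family_exome(cfg)
  expr <- gen_tissue_matrix(cfg, genes = sim$variants$variants$gene)
  rep <- prioritize_pipeline(sim$variants, sim$pedigree,
                             specificity_scores(expr), mode = "both")
  counts <- attr(rep, "stage_counts")
  expect_true(all(diff(counts) <= 0))
  expect_identical(rep$key[rep$rank == 1L], sim$planted_key)

  ## empty input yields an empty report
  empty <- meioscan:::subset_variant_set(sim$variants,
                                         rep(FALSE, n_variants(sim$variants)))
  rep0 <- prioritize_pipeline(empty, sim$pedigree, specificity_scores(expr))
  expect_identical(nrow(rep0), 0L)
})
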