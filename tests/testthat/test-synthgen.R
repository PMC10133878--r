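test_that("every generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 42, n_variants = 100, n_cells_fish = 50,
                    scrna = list(n_clusters = 3, cells_per_cluster = 20))
  panel <- fish_panel(c("X", "Y", "18"))
  expect_identical(gen_family_exome(cfg), gen_family_exome(cfg))
  expect_identical(gen_tissue_matrix(cfg, n_genes = 50),
                   gen_tissue_matrix(cfg, n_genes = 50))
  expect_identical(gen_scrna(cfg), gen_scrna(cfg))
  expect_identical(gen_fish_cells(cfg, panel), gen_fish_cells(cfg, panel))
  expect_identical(gen_fertility(cfg), gen_fertility(cfg))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(n_variants = 0), "n_variants")
  expect_error(sim_config(p_aneuploid = 1.2), "probabilities")
  expect_error(sim_config(inbreeding = -0.1), "probabilities")
  expect_error(sim_config(fertility_means = c(wt = 100, mut = 0)), "positive")
  expect_error(sim_config(planted = list(gene = "G", chrom = "1",
                                         consequence = "missense",
                                         maf = 1e-4)),
               "stop_gained")
})

test_that("the planted variant satisfies recessive segregation in every replicate", {
  for (s in 1:100) {
    sim <- gen_family_exome(sim_config(seed = s, n_variants = 5))
    g <- sim$variants$geno[sim$variants$variants$key == sim$planted_key, ]
    expect_true(all(g[c("P1", "P2")] == "hom-alt"))
    expect_true(all(g[c("F", "M")] == "het"))
    expect_true(g["B3"] %in% c("het", "hom-ref"))
    expect_false(any(g[sim$pedigree$controls] == "hom-alt"))
  }
})

test_that("background MAF spectrum matches the configured Beta distribution", {
  cfg <- sim_config(seed = 9, n_variants = 5000, maf_missing_rate = 0)
  sim <- gen_family_exome(cfg)
  maf <- sim$variants$variants$maf
  maf <- maf[sim$variants$variants$key != sim$planted_key]
  ## quadrature oracle for P(Beta(0.5, 10) < 0.01)
  p <- integrate(function(x) dbeta(x, 0.5, 10), 0, 0.01)$value
  observed <- sum(maf < 0.01)
  ci <- qbinom(c(0.005, 0.995), 5000, p)   # 99% binomial band
  expect_gte(observed, ci[1])
  expect_lte(observed, ci[2])
})

test_that("planted-common MAF is allowed but flagged in metadata", {
  cfg <- sim_config(seed = 1, n_variants = 20,
                    planted = list(gene = "G", chrom = "14",
                                   consequence = "stop_gained", maf = 0.05))
  sim <- gen_family_exome(cfg)
  expect_true(attr(sim$variants, "planted_flagged_common"))
  expect_false(attr(gen_family_exome(sim_config(seed = 1, n_variants = 20))$variants,
                    "planted_flagged_common"))
})

test_that("tissue matrix has the planted ground-truth structure", {
  cfg <- sim_config(seed = 5)
  mat <- gen_tissue_matrix(cfg, n_genes = 400)
  truth <- attr(mat, "truth")
  expect_true(all(mat >= 0))
  excl <- names(truth)[truth == "testis_exclusive"]
  silent <- names(truth)[truth == "silent"]
  expect_true(all(mat[excl, "testis"] > 0))
  expect_true(all(mat[excl, setdiff(colnames(mat), "testis")] == 0))
  expect_true(all(mat[silent, ] == 0))
  expect_error(gen_tissue_matrix(cfg, tissues = "testis"), "2 tissues")

  ## every testis-exclusive gene outranks every broad gene on specificity
  spec <- specificity_scores(mat)
  r <- setNames(spec$r, spec$gene)
  broad <- names(truth)[truth == "broad"]
  expect_gt(min(r[excl]), max(r[broad]))
})

test_that("single-cell generator produces marker structure and library-size variation", {
  cfg <- sim_config(seed = 13)   # default: 10 clusters x 100 cells, 4-fold
  sc <- gen_scrna(cfg)
  totals <- colSums(sc$counts)
  expect_gt(sd(totals), 0)
  ann <- sc$annotation
  for (i in seq_along(sc$markers)) {
    own <- ann$cluster == i
    for (g in sc$markers[[i]]) {
      own_mean <- mean(sc$counts[g, own])
      other_means <- vapply(setdiff(seq_along(sc$markers), i), function(j)
        mean(sc$counts[g, ann$cluster == j]), numeric(1))
      expect_gt(own_mean, max(other_means))
    }
  }
})

test_that("FISH generator hits the configured normal-ploidy rate", {
  panel <- fish_panel(c("X", "Y", "18"))
  cfg0 <- sim_config(seed = 3, p_aneuploid = 0, n_cells_fish = 100)
  cells0 <- gen_fish_cells(cfg0, panel)
  expect_true(all(classify_cells(cells0, panel) == "normal"))

  cfg <- sim_config(seed = 3, p_aneuploid = 0.883, n_cells_fish = 500)
  cells <- gen_fish_cells(cfg, panel)
  obs <- mean(classify_cells(cells, panel) == "normal")
  half <- 1.96 * sqrt(0.117 * 0.883 / 500)   # 95% binomial band around truth
  expect_lt(abs(obs - 0.117), half + 1e-12)
})

test_that("generated FISH truth labels agree with the classifier", {
  panel <- fish_panel(c("X", "Y", "18"))
  cells <- gen_fish_cells(sim_config(seed = 21, n_cells_fish = 300), panel)
  expect_identical(unname(classify_cells(cells, panel)), cells$truth)
  panel_a <- fish_panel(c("13", "21", "22"))
  cells_a <- gen_fish_cells(sim_config(seed = 22, n_cells_fish = 300), panel_a)
  expect_identical(unname(classify_cells(cells_a, panel_a)), cells_a$truth)
})

test_that("fertility generator recovers configured effect sizes", {
  ## equal means: average estimated reduction within +/- 2% of zero
  red_null <- vapply(1:200, function(s) {
    f <- gen_fertility(sim_config(seed = s,
                                  fertility_means = c(wt = 100, mut = 100)))
    fertility_compare(f$progeny[f$genotype == "mut"],
                      f$progeny[f$genotype == "wt"])$percent_reduction
  }, numeric(1))
  expect_lt(abs(mean(red_null)), 2)

  ## 30% true reduction recovered on average
  red_eff <- vapply(1:200, function(s) {
    f <- gen_fertility(sim_config(seed = 10000 + s,
                                  fertility_means = c(wt = 100, mut = 70)))
    fertility_compare(f$progeny[f$genotype == "mut"],
                      f$progeny[f$genotype == "wt"])$percent_reduction
  }, numeric(1))
  expect_lt(abs(mean(red_eff) - 30), 2)
})
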