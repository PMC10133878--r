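ecori <- enzyme("EcoRI", "GAATTC", 1)

test_that("restriction digestion reproduces manual scans and conserves length", {
  expect_identical(digest("AAGAATTCTT", ecori), c(3L, 7L))
  expect_identical(digest("ACGTACGTACGT", ecori), 12L)  # no site: one fragment
  expect_error(digest("", ecori), "empty")
  expect_error(digest("ACGN", ecori), "unambiguous")

  ## IUPAC expansion in the site: GGWCC matches GGACC and GGTCC
  hae <- enzyme("AvaII_like", "GGWCC", 2)
  expect_identical(digest("AAGGACCAAGGTCCAA", hae), c(4L, 7L, 5L))

  set.seed(91)
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(20:120, 1),
                      replace = TRUE), collapse = "")
    expect_identical(sum(digest(s, ecori)), nchar(s))
  }
})

test_that("non-palindromic sites are found on both strands, with mirror symmetry", {
  ## BspMI-like asymmetric site
  enz <- enzyme("Asym", "ACCTGC", 4)
  s <- "TTTACCTGCTTTTTGCAGGTTTT"   # site on top strand and on bottom strand
  fr <- digest(s, enz)
  expect_identical(sum(fr), nchar(s))
  expect_gt(length(fr), 2L)   # both orientations cut
  ## digesting the reverse complement reverses the fragment list
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_identical(digest(rc, enz), rev(fr))

  set.seed(92)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_identical(digest(rc, enz), rev(digest(s, enz)))
  }
})

test_that("allele discrimination detects site gain/loss between alleles", {
  ## variant destroys the only EcoRI site: ref [3,7] vs alt [10]
  amp <- amplicon("AAGAATTCTT", variant_offset = 4L, ref = "A", alt = "C")
  d <- allele_discrimination(amp, ecori)
  expect_identical(d$ref_fragments, c(3L, 7L))
  expect_identical(d$alt_fragments, 10L)
  expect_true(d$discriminates)

  ## variant outside any site: identical patterns
  amp2 <- amplicon("AAGAATTCTT", variant_offset = 9L, ref = "T", alt = "A")
  d2 <- allele_discrimination(amp2, ecori)
  expect_false(d2$discriminates)

  ## genotype calling from observed patterns
  expect_identical(call_rflp_genotype(list(d$ref_fragments), d), "hom-ref")
  expect_identical(call_rflp_genotype(list(d$alt_fragments), d), "hom-alt")
  expect_identical(call_rflp_genotype(list(d$ref_fragments, d$alt_fragments),
                                      d), "het")
})

test_that("mismatch-site design finds single-base substitutions spanning the variant", {
  ## ref carries GTATTC around the variant (offset 14, A>G); a T->A mismatch
  ## at offset 13 creates GAATTC across the variant on the ref allele only
  seq <- paste0("ACGTACGTACGT", "GTATTC", "GTACGTACGTAC")
  amp <- amplicon(seq, variant_offset = 14L, ref = "A", alt = "G")
  designs <- design_mismatch_site(amp, list(ecori), primer_window = 6L)
  expect_false(attr(designs, "not_needed"))
  expect_true(any(designs$enzyme == "EcoRI" & designs$position == 13L &
                    designs$base == "A" & designs$cut_allele == "ref"))

  ## self-consistency: every returned design discriminates the alleles
  for (i in seq_len(nrow(designs))) {
    mseq <- seq
    substr(mseq, designs$position[i] + 1L, designs$position[i] + 1L) <-
      designs$base[i]
    mamp <- amplicon(mseq, 14L, "A", "G")
    expect_true(allele_discrimination(mamp, ecori)$discriminates)
  }

  ## already discriminable: empty result flagged not-needed
  amp_nat <- amplicon("TTTTTTGAATTCTTTTTT", variant_offset = 8L,
                      ref = "A", alt = "C")
  d0 <- design_mismatch_site(amp_nat, list(ecori), primer_window = 6L)
  expect_identical(nrow(d0), 0L)
  expect_true(attr(d0, "not_needed"))

  ## deterministic ordering regardless of enzyme list order
  other <- enzyme("Other", "GGTACC", 1)
  d1 <- design_mismatch_site(amp, list(ecori, other), primer_window = 6L)
  d2 <- design_mismatch_site(amp, list(other, ecori), primer_window = 6L)
  expect_identical(d1, d2)

  expect_error(design_mismatch_site(amp, list(ecori), primer_window = 3L),
               "site length")
  expect_error(design_mismatch_site(amp, list(ecori), primer_window = 20L),
               "bounds")
})

test_that("coding substitution annotation reproduces a premature opal stop", {
  ## codon 150 = CGA (Arg); c.448C>T converts it to TGA
  cds <- paste0(strrep("GCT", 149), "CGA", strrep("GCT", 50))
  cc <- annotate_cds_substitution(cds, 448, "C", "T")
  expect_identical(cc$codon_index, 150L)
  expect_identical(cc$ref_codon, "CGA")
  expect_identical(cc$alt_codon, "TGA")
  expect_identical(cc$protein, "p.R150X")
  expect_identical(cc$consequence, "stop_gained")
  expect_identical(cc$stop_class, "opal")

  ## same substitution in a CGC codon is missense, not a stop
  cds2 <- paste0(strrep("GCT", 149), "CGC", strrep("GCT", 50))
  cc2 <- annotate_cds_substitution(cds2, 448, "C", "T")
  expect_identical(cc2$alt_codon, "TGC")
  expect_identical(cc2$protein, "p.R150C")
  expect_identical(cc2$consequence, "missense")
  expect_identical(cc2$stop_class, "none")

  ## third-position synonymous change
  cc3 <- annotate_cds_substitution(cds, 450, "A", "G")  # CGA -> CGG (Arg)
  expect_identical(cc3$consequence, "synonymous")

  ## stop classes by alternate codon
  cds_amber <- paste0("ATG", "TAC", strrep("GCT", 8))
  expect_identical(annotate_cds_substitution(cds_amber, 6, "C", "G")$stop_class,
                   "amber")   # TAC -> TAG
  cds_ochre <- paste0("ATG", "TAC", strrep("GCT", 8))
  expect_identical(annotate_cds_substitution(cds_ochre, 6, "C", "A")$stop_class,
                   "ochre")   # TAC -> TAA

  ## round trip: re-annotating the mutated CDS restores the original codon
  mut <- cds; substr(mut, 448, 448) <- "T"
  back <- annotate_cds_substitution(mut, 448, "T", "C")
  expect_identical(back$alt_codon, cc$ref_codon)

  expect_error(annotate_cds_substitution(cds, 448, "G", "T"), "reference base")
  expect_error(annotate_cds_substitution(paste0(cds, "A"), 448, "C", "T"),
               "divisible")
})

test_that("flanking-haplotype comparison counts marker matches", {
  gt_a <- setNames(lapply(1:12, function(i) c(100 + i, 110 + i)),
                   c(sprintf("MS_UP%d", 1:8), sprintf("MS_DN%d", 1:4)))
  gt_b <- gt_a
  panel <- microsat_panel(genotypes = list(P1 = gt_a, PS1 = gt_b))
  res <- compare_flanking_haplotypes(panel, "P1", "PS1")
  expect_equal(res[c("n_markers_compared", "n_matching")],
               list(n_markers_compared = 12L, n_matching = 12L))
  expect_true(res$shared_verdict)

  ## unordered allele pairs: swapped order still matches
  gt_b$MS_UP1 <- rev(gt_b$MS_UP1)
  panel2 <- microsat_panel(genotypes = list(P1 = gt_a, PS1 = gt_b))
  expect_true(compare_flanking_haplotypes(panel2, "P1", "PS1")$shared_verdict)

  ## one marker differing
  gt_b$MS_DN2 <- c(95, 97)
  panel3 <- microsat_panel(genotypes = list(P1 = gt_a, PS1 = gt_b))
  res3 <- compare_flanking_haplotypes(panel3, "P1", "PS1")
  expect_equal(res3$n_matching, 11L)
  expect_false(res3$shared_verdict)
  expect_identical(res3$mismatching_markers, "MS_DN2")

  ## partial genotyping: only common markers compared
  gt_c <- gt_a[1:10]
  panel4 <- microsat_panel(genotypes = list(P1 = gt_a, PS1 = gt_c))
  expect_equal(compare_flanking_haplotypes(panel4, "P1", "PS1")$n_markers_compared,
               10L)

  panel5 <- microsat_panel(genotypes = list(P1 = gt_a[1:6], PS1 = gt_a[7:12]))
  expect_error(compare_flanking_haplotypes(panel5, "P1", "PS1"), "common")
})
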