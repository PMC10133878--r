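#' Define a restriction enzyme
#'
#' @param name enzyme name, e.g. `"EcoRI"`.
#' @param site recognition site as an IUPAC string (length >= 4); ambiguity
#'   codes are expanded during matching.
#' @param cut_offset top-strand cut position within the site, in
#'   `[0, nchar(site)]` — the number of site bases left of the cut.
#' @return object of class `enzyme`.
#' @export
#' @examples
#' enzyme("EcoRI", "GAATTC", 1)
enzyme <- function(name, site, cut_offset) {
  site <- toupper(site)
  if (nchar(site) < 4L) stop("recognition site must be >= 4 bases")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", site)) stop("invalid IUPAC site: ", site)
  if (cut_offset < 0 || cut_offset > nchar(site))
    stop("cut offset must lie within the site")
  structure(list(name = name, site = site, cut_offset = as.integer(cut_offset)),
            class = "enzyme")
}

check_dna <- function(sequence) {
  sequence <- toupper(sequence)
  if (!nchar(sequence)) stop("empty sequence")
  if (!grepl("^[ACGT]+$", sequence))
    stop("sequence must be unambiguous A/C/G/T")
  sequence
}

revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

## 0-based between-base cut coordinates for all double-strand cuts of `enz`
## in `sequence`; bottom-strand recognition located via the reverse
## complement of the site, cutting at (match end - cut_offset) on top.
cut_positions <- function(sequence, enz) {
  subject <- Biostrings::DNAString(sequence)
  top <- Biostrings::matchPattern(enz$site, subject, fixed = FALSE)
  cuts <- Biostrings::start(top) - 1L + enz$cut_offset
  rc_site <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(enz$site)))
  if (rc_site != enz$site) {
    bottom <- Biostrings::matchPattern(rc_site, subject, fixed = FALSE)
    cuts <- c(cuts, Biostrings::end(bottom) - enz$cut_offset)
  }
  sort(unique(cuts[cuts > 0L & cuts < nchar(sequence)]))
}

#' In-silico restriction digestion
#'
#' Cuts the sequence at every match of the enzyme's recognition site (IUPAC
#' codes expanded) on either strand — non-palindromic sites are additionally
#' searched as their reverse complement — and returns the ordered fragment
#' lengths, which always sum to the input length. Digestion is assumed
#' complete (no partial digestion products).
#'
#' @param sequence unambiguous DNA string (A/C/G/T).
#' @param enz an [enzyme()].
#' @return integer vector of fragment lengths, left to right.
#' @export
#' @examples
#' digest("AAGAATTCTT", enzyme("EcoRI", "GAATTC", 1))  # 3, 7
digest <- function(sequence, enz) {
  sequence <- check_dna(sequence)
  cuts <- cut_positions(sequence, enz)
  as.integer(diff(c(0L, cuts, nchar(sequence))))
}

#' Construct an amplicon around a variant
#'
#' @param sequence reference-allele amplicon sequence (A/C/G/T).
#' @param variant_offset 0-based offset of the variant base.
#' @param ref,alt single reference / alternate bases; the sequence must carry
#'   `ref` at the offset.
#' @return object of class `amplicon`.
#' @export
amplicon <- function(sequence, variant_offset, ref, alt) {
  sequence <- check_dna(sequence)
  if (variant_offset < 0 || variant_offset >= nchar(sequence))
    stop("variant offset outside sequence")
  if (substr(sequence, variant_offset + 1L, variant_offset + 1L) != ref)
    stop("sequence does not carry the reference base at the variant offset")
  if (!alt %in% c("A", "C", "G", "T") || alt == ref)
    stop("alt must be a base different from ref")
  structure(list(sequence = sequence,
                 variant_offset = as.integer(variant_offset),
                 ref = ref, alt = alt),
            class = "amplicon")
}

alt_sequence <- function(amp) {
  s <- amp$sequence
  substr(s, amp$variant_offset + 1L, amp$variant_offset + 1L) <- amp$alt
  s
}

#' RFLP allele discrimination
#'
#' Digests both allelic versions of an amplicon and reports whether the
#' fragment patterns differ (as multisets of lengths), i.e. whether the
#' enzyme distinguishes the two alleles on a gel.
#'
#' @param amp an [amplicon()].
#' @param enz an [enzyme()].
#' @return list: `ref_fragments`, `alt_fragments`, `discriminates`.
#' @export
allele_discrimination <- function(amp, enz) {
  stopifnot(inherits(amp, "amplicon"))
  ref_fr <- digest(amp$sequence, enz)
  alt_fr <- digest(alt_sequence(amp), enz)
  list(ref_fragments = ref_fr, alt_fragments = alt_fr,
       discriminates = !identical(sort(ref_fr), sort(alt_fr)))
}

#' Call a genotype from observed RFLP fragment patterns
#'
#' @param observed list of observed fragment-length multisets (a homozygote
#'   shows one pattern; a heterozygote shows the union of both).
#' @param discrimination result of [allele_discrimination()].
#' @return `"hom-ref"`, `"hom-alt"` or `"het"`.
#' @export
call_rflp_genotype <- function(observed, discrimination) {
  if (!discrimination$discriminates)
    stop("enzyme does not discriminate the alleles")
  ref_p <- sort(discrimination$ref_fragments)
  alt_p <- sort(discrimination$alt_fragments)
  obs <- sort(unique(unlist(observed)))
  has_ref <- all(ref_p %in% obs)
  has_alt <- all(alt_p %in% obs)
  if (has_ref && has_alt) "het"
  else if (has_ref) "hom-ref"
  else if (has_alt) "hom-alt"
  else stop("observed fragments match neither allele pattern")
}

#' Mismatch-primer restriction-site design
#'
#' When no natural site distinguishes the alleles, a deliberate single-base
#' mismatch in the PCR primer can create a diagnostic site that spans the
#' variant in exactly one allele. This performs the exhaustive search: every
#' single-base substitution within `primer_window` bases on either side of
#' the variant (the variant base itself excluded), against every enzyme,
#' keeping substitutions for which exactly one allele gains a recognition
#' match overlapping the variant position. Results are ordered
#' deterministically by (enzyme, position, base).
#'
#' @param amp an [amplicon()].
#' @param enzymes list of [enzyme()] objects.
#' @param primer_window how many bases each side of the variant to mutate;
#'   must be at least the longest site length and stay inside the amplicon.
#' @return data.frame `enzyme`, `position` (0-based substitution offset),
#'   `base`, `cut_allele` (`"ref"` or `"alt"`); attribute `not_needed = TRUE`
#'   (with zero rows) when some supplied enzyme already discriminates the
#'   unmodified amplicon.
#' @export
design_mismatch_site <- function(amp, enzymes, primer_window) {
  stopifnot(inherits(amp, "amplicon"))
  if (inherits(enzymes, "enzyme")) enzymes <- list(enzymes)
  max_site <- max(vapply(enzymes, function(e) nchar(e$site), integer(1)))
  if (primer_window < max_site)
    stop("primer_window must cover at least the longest site length")
  off <- amp$variant_offset
  len <- nchar(amp$sequence)
  if (off - primer_window < 0L || off + primer_window >= len)
    stop("primer_window exceeds amplicon bounds")

  already <- vapply(enzymes, function(e)
    allele_discrimination(amp, e)$discriminates, logical(1))
  if (any(already)) {
    out <- data.frame(enzyme = character(), position = integer(),
                      base = character(), cut_allele = character())
    attr(out, "not_needed") <- TRUE
    return(out)
  }

  ref_seq <- amp$sequence
  alt_seq <- alt_sequence(amp)
  positions <- setdiff(seq(off - primer_window, off + primer_window), off)
  rows <- list()
  enz_names <- vapply(enzymes, `[[`, character(1), "name")
  for (ei in order(enz_names)) {
    e <- enzymes[[ei]]
    for (pos in positions) {
      cur <- substr(ref_seq, pos + 1L, pos + 1L)
      for (b in setdiff(c("A", "C", "G", "T"), cur)) {
        mref <- ref_seq; substr(mref, pos + 1L, pos + 1L) <- b
        malt <- alt_seq; substr(malt, pos + 1L, pos + 1L) <- b
        ref_hit <- site_overlaps_variant(mref, e, off)
        alt_hit <- site_overlaps_variant(malt, e, off)
        if (xor(ref_hit, alt_hit)) {
          rows[[length(rows) + 1L]] <- data.frame(
            enzyme = e$name, position = pos, base = b,
            cut_allele = if (ref_hit) "ref" else "alt",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(enzyme = character(), position = integer(),
                  base = character(), cut_allele = character())
  attr(out, "not_needed") <- FALSE
  rownames(out) <- NULL
  out
}

site_overlaps_variant <- function(sequence, enz, offset0) {
  subject <- Biostrings::DNAString(sequence)
  pats <- unique(c(enz$site, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(enz$site)))))
  for (p in pats) {
    m <- Biostrings::matchPattern(p, subject, fixed = FALSE)
    if (length(m) &&
        any(Biostrings::start(m) - 1L <= offset0 &
            Biostrings::end(m) - 1L >= offset0))
      return(TRUE)
  }
  FALSE
}

#' Annotate a coding single-base substitution
#'
#' Locates the affected codon of an in-frame CDS, translates reference and
#' alternate codons with the standard genetic code, and reports the protein
#' consequence in HGVS-like notation (e.g. `p.R150X` for a premature stop).
#' Stop codons are classed as amber (TAG), ochre (TAA) or opal (TGA).
#'
#' @param cds in-frame coding sequence (length divisible by 3, A/C/G/T).
#' @param position 1-based CDS position of the substitution.
#' @param ref,alt reference and alternate bases; the CDS must carry `ref` at
#'   `position` (hard error otherwise).
#' @return a `coding_change`: list with `cds_position`, `codon_index`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `protein` (HGVS-like),
#'   `consequence` (`stop_gained` / `missense` / `synonymous` / `stop_lost`),
#'   `stop_class` (`amber` / `ochre` / `opal` / `none`).
#' @export
#' @examples
#' cds <- paste(rep("GCT", 200), collapse = "")
#' substr(cds, 448, 450) <- "CGA"   # codon 150 = CGA (Arg)
#' annotate_cds_substitution(cds, 448, "C", "T")$protein  # p.R150X
annotate_cds_substitution <- function(cds, position, ref, alt) {
  cds <- check_dna(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS length must be divisible by 3")
  if (position < 1L || position > nchar(cds)) stop("position outside CDS")
  if (substr(cds, position, position) != ref)
    stop("CDS carries ", substr(cds, position, position), " at position ",
         position, ", not the stated reference base ", ref)
  if (!alt %in% c("A", "C", "G", "T") || alt == ref)
    stop("alt must be a base different from ref")

  codon_index <- ceiling(position / 3)
  within <- (position - 1L) %% 3L + 1L
  codon_start <- (codon_index - 1L) * 3L + 1L
  ref_codon <- substr(cds, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt

  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  stop_class <- switch(alt_codon, TAG = "amber", TAA = "ochre",
                       TGA = "opal", "none")
  consequence <- if (alt_aa == "*" && ref_aa != "*") "stop_gained"
    else if (ref_aa == "*" && alt_aa != "*") "stop_lost"
    else if (ref_aa == alt_aa) "synonymous"
    else "missense"
  protein <- paste0("p.", sub("\\*", "X", ref_aa), codon_index,
                    if (alt_aa == "*") "X" else alt_aa)
  structure(list(cds_position = as.integer(position),
                 codon_index = as.integer(codon_index),
                 ref_codon = ref_codon, alt_codon = alt_codon,
                 ref_aa = ref_aa, alt_aa = alt_aa, protein = protein,
                 consequence = consequence,
                 stop_class = if (consequence == "stop_gained") stop_class
                              else "none"),
            class = "coding_change")
}

#' @export
print.coding_change <- function(x, ...) {
  cat("c.", x$cds_position, ": ", x$ref_codon, " -> ", x$alt_codon,
      " (codon ", x$codon_index, "), ", x$protein, " [", x$consequence,
      if (x$stop_class != "none") paste0(", ", x$stop_class, " stop"), "]\n",
      sep = "")
  invisible(x)
}

#' Construct a microsatellite marker panel with per-individual genotypes
#'
#' The default marker layout mirrors the flanking design around a candidate
#' gene: eight markers upstream within 2 Mb and four downstream within
#' 0.7 Mb.
#'
#' @param markers data.frame with `name`, `offset_bp` (distance from the
#'   gene), `side` (`"upstream"`/`"downstream"`); NULL for the default
#'   12-marker layout.
#' @param genotypes named list: individual id -> named list of marker ->
#'   numeric allele-length pair.
#' @return object of class `microsat_panel`.
#' @export
microsat_panel <- function(markers = NULL, genotypes = list()) {
  if (is.null(markers)) {
    markers <- data.frame(
      name = c(sprintf("MS_UP%d", 1:8), sprintf("MS_DN%d", 1:4)),
      offset_bp = c(round(seq(2e5, 2e6, length.out = 8)),
                    round(seq(1.5e5, 7e5, length.out = 4))),
      side = c(rep("upstream", 8), rep("downstream", 4)),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "offset_bp", "side") %in% names(markers)))
  if (any(markers$offset_bp <= 0)) stop("marker offsets must be positive")
  up <- markers$side == "upstream"
  if (any(markers$offset_bp[up] > 2e6) || any(markers$offset_bp[!up] > 7e5))
    stop("markers outside the flanking window (2 Mb up / 0.7 Mb down)")
  for (ind in names(genotypes)) {
    for (mk in names(genotypes[[ind]])) {
      al <- genotypes[[ind]][[mk]]
      if (length(al) != 2L || any(al <= 0))
        stop("genotype for ", ind, "/", mk,
             " must be a pair of positive allele lengths")
    }
  }
  structure(list(markers = markers, genotypes = genotypes),
            class = "microsat_panel")
}

#' Compare microsatellite flanking haplotypes between two individuals
#'
#' Tests whether two carriers of the same variant share the flanking genetic
#' background: for every marker genotyped in both individuals, the unordered
#' allele-length pairs are compared; the backgrounds are called shared only
#' if all compared markers match.
#'
#' @param panel a [microsat_panel()].
#' @param a,b individual ids present in the panel's genotypes.
#' @return list: `n_markers_compared`, `n_matching`, `shared_verdict`,
#'   `mismatching_markers`.
#' @export
compare_flanking_haplotypes <- function(panel, a, b) {
  stopifnot(inherits(panel, "microsat_panel"))
  ga <- panel$genotypes[[a]]
  gb <- panel$genotypes[[b]]
  if (is.null(ga) || is.null(gb)) stop("individual(s) not genotyped")
  common <- intersect(names(ga), names(gb))
  common <- intersect(common, panel$markers$name)
  if (!length(common)) stop("no common genotyped markers between ", a,
                            " and ", b)
  match_ok <- vapply(common, function(mk)
    identical(sort(as.numeric(ga[[mk]])), sort(as.numeric(gb[[mk]]))),
    logical(1))
  list(n_markers_compared = length(common),
       n_matching = sum(match_ok),
       shared_verdict = all(match_ok),
       mismatching_markers = common[!match_ok])
}
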