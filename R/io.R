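## File interchange: VCF v4.2 (GT-only) + PED + annotation TSV for exomes,
## plain TSV for matrices, FISH tables and fertility trials.

gt_code <- c("hom-ref" = "0/0", "het" = "0/1", "hom-alt" = "1/1",
             "hemi-ref" = "0", "hemi-alt" = "1", "missing" = "./.")
gt_decode <- setNames(names(gt_code), gt_code)

#' Write a variant set as VCF v4.2 (GT-only), PED pedigree and annotation TSV
#'
#' @param sim output of [gen_family_exome()] (or a list with `variants` and
#'   `pedigree`).
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return invisibly, the three file paths (`vcf`, `ped`, `ann`).
#' @export
write_exome_bundle <- function(sim, dir, prefix = "exome") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- sim$variants; ped <- sim$pedigree
  samples <- colnames(vs$geno)

  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  header <- c("##fileformat=VCFv4.2",
              "##source=meioscan",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  gt <- matrix(gt_code[vs$geno], nrow = nrow(vs$geno))
  body <- apply(cbind(vs$variants$chrom, vs$variants$pos, vs$variants$key,
                      vs$variants$ref, vs$variants$alt, ".", "PASS", ".",
                      "GT", gt), 1L, paste, collapse = "\t")
  writeLines(c(header, body), vcf_path)

  ped_path <- file.path(dir, paste0(prefix, ".ped"))
  m <- ped$members
  fam_rows <- data.frame(fid = "FAM1", iid = m$id,
                         father = ifelse(is.na(m$father), "0", m$father),
                         mother = ifelse(is.na(m$mother), "0", m$mother),
                         sex = ifelse(m$sex == "male", 1L, 2L),
                         phenotype = c(yes = 2L, no = 1L, unknown = 0L)[m$affected])
  ctl_rows <- if (length(ped$controls))
    data.frame(fid = ped$controls, iid = ped$controls, father = "0",
               mother = "0", sex = 1L, phenotype = 1L)
  write.table(rbind(fam_rows, ctl_rows), ped_path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)

  ann_path <- file.path(dir, paste0(prefix, "_annotation.tsv"))
  write.table(vs$variants[, c("key", "gene", "consequence", "maf",
                              "conservation")],
              ann_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(vcf = vcf_path, ped = ped_path, ann = ann_path))
}

#' Read a VCF + PED + annotation bundle into a variant set and pedigree
#'
#' The VCF is parsed with vcfR; genotypes are mapped to the package's state
#' vocabulary (`0/0`, `0|0` -> hom-ref; `0/1`, `1/0` -> het; `1/1` ->
#' hom-alt; haploid `0`/`1` -> hemi-ref/hemi-alt; anything missing ->
#' missing). Family members are the rows of the PED family with an affected
#' member; unaffected single-member families are the control cohort.
#'
#' @param vcf,ped,ann file paths as written by [write_exome_bundle()].
#' @return list with `variants` ([variant_set()]) and `pedigree`
#'   ([pedigree()]).
#' @export
read_exome_bundle <- function(vcf, ped, ann) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  decode1 <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- gt_decode[g]
    out[g %in% c("1/0")] <- "het"
    out[is.na(out) | g %in% c("./.", ".")] <- "missing"
    out
  }
  geno <- matrix(decode1(gt_raw), nrow = nrow(gt_raw),
                 dimnames = dimnames(gt_raw))

  ann_tab <- read.table(ann, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  key <- paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":")
  idx <- match(key, ann_tab$key)
  if (anyNA(idx)) stop("annotation table lacks ", sum(is.na(idx)), " variant(s)")
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         gene = ann_tab$gene[idx],
                         consequence = ann_tab$consequence[idx],
                         maf = ann_tab$maf[idx],
                         conservation = ann_tab$conservation[idx],
                         stringsAsFactors = FALSE)

  ped_tab <- read.table(ped, header = FALSE, sep = "\t",
                        col.names = c("fid", "iid", "father", "mother",
                                      "sex", "phenotype"),
                        stringsAsFactors = FALSE)
  fam_ids <- unique(ped_tab$fid[ped_tab$phenotype == 2L])
  fam <- ped_tab[ped_tab$fid %in% fam_ids, ]
  ctl <- ped_tab$iid[!ped_tab$fid %in% fam_ids]
  members <- data.frame(
    id = fam$iid, sex = ifelse(fam$sex == 1L, "male", "female"),
    affected = c("0" = "unknown", "1" = "no", "2" = "yes")[
      as.character(fam$phenotype)],
    father = ifelse(fam$father == "0", NA_character_, fam$father),
    mother = ifelse(fam$mother == "0", NA_character_, fam$mother),
    stringsAsFactors = FALSE)
  list(variants = variant_set(variants, geno),
       pedigree = pedigree(members, ctl))
}

#' Write / read a genes x columns numeric matrix as TSV
#'
#' @param mat numeric matrix with row and column names.
#' @param path TSV file path.
#' @return `write_matrix_tsv` returns the path invisibly; `read_matrix_tsv`
#'   returns the matrix (with a `target_tissue` attribute when `target` is
#'   given).
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param target optional target-tissue name recorded as an attribute.
#' @export
read_matrix_tsv <- function(path, target = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  if (!is.null(target)) attr(mat, "target_tissue") <- target
  mat
}

#' Write a candidate report as TSV and JSON
#'
#' @param report a `candidate_report` from [prioritize_pipeline()].
#' @param path_tsv,path_json output paths (either may be NULL to skip).
#' @param seed,version provenance stamps recorded in the JSON.
#' @return invisibly, the written paths.
#' @export
write_candidate_report <- function(report, path_tsv = NULL, path_json = NULL,
                                   seed = NA, version =
                                     as.character(packageVersion("meioscan"))) {
  if (!is.null(path_tsv))
    write.table(as.data.frame(report), path_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(path_json)) {
    payload <- list(seed = seed, version = version,
                    stage_counts = as.list(attr(report, "stage_counts")),
                    candidates = as.data.frame(report))
    jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(tsv = path_tsv, json = path_json))
}
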