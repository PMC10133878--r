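#' Exclusive-expression indicator vector
#'
#' The synthetic reference profile of a gene expressed in exactly one tissue:
#' 1 at the target tissue, 0 elsewhere. Pearson correlation is invariant to
#' positive affine rescaling, so any positive constant in place of 1 yields
#' identical specificity scores.
#'
#' @param tissues character vector of tissue names.
#' @param target the designated tissue; must appear in `tissues`.
#' @return named numeric vector over `tissues`.
#' @export
#' @examples
#' synthetic_vector(c("testis", "liver", "brain"), "testis")
synthetic_vector <- function(tissues, target) {
  if (!target %in% tissues) stop("target tissue absent: ", target)
  setNames(as.numeric(tissues == target), tissues)
}

#' Tissue-specificity scores by correlation with an exclusive profile
#'
#' For every gene, the Pearson product-moment correlation r between its
#' cross-tissue TPM vector and the exclusive-expression indicator for the
#' target tissue. The closer r is to 1 the more specific the gene's
#' expression is to the target. Genes with zero variance across tissues
#' (constant TPM, including all-zero silent genes) have no defined correlation
#' and are flagged undefined and ranked last.
#'
#' @param mat numeric genes x tissues matrix of non-negative TPM values, with
#'   gene rownames and tissue colnames. A `target_tissue` attribute (as set by
#'   [gen_tissue_matrix()]) supplies the default target.
#' @param target target tissue column name (default `"testis"` or the
#'   matrix's `target_tissue` attribute).
#' @return a `specificity_result`: data.frame `gene`, `r` (NA when undefined),
#'   `defined`, `rank` — ordered by r descending, undefined genes last.
#' @export
#' @examples
#' m <- rbind(tse = c(8, 1, 1), broad = c(5, 6, 4), silent = c(0, 0, 0))
#' colnames(m) <- c("testis", "liver", "brain")
#' specificity_scores(m)
specificity_scores <- function(mat, target = NULL) {
  if (is.null(target))
    target <- attr(mat, "target_tissue") %||% "testis"
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need >= 2 tissues to correlate against")
  if (any(mat < 0)) stop("TPM values must be non-negative")
  v <- synthetic_vector(colnames(mat), target)

  n <- ncol(mat)
  rs <- rowSums(mat)
  centered <- mat - rs / n
  vc <- v - mean(v)
  denom <- sqrt(rowSums(centered^2) * sum(vc^2))
  r <- as.numeric(centered %*% vc) / denom
  r[denom == 0] <- NA_real_

  defined <- !is.na(r)
  ord <- order(!defined, -ifelse(defined, r, -Inf))
  out <- data.frame(gene = rownames(mat)[ord], r = r[ord],
                    defined = defined[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  structure(out, target = target,
            class = c("specificity_result", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.specificity_result <- function(x, n = 10L, ...) {
  cat("Testis-specificity scores (target: ", attr(x, "target"), "), ",
      nrow(x), " genes, ", sum(!x$defined), " undefined\n", sep = "")
  print.data.frame(utils::head(x, n))
  invisible(x)
}
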