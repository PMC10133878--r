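#' Counts-per-million normalization
#'
#' Rescales each cell (column) so its counts sum to one million. Cells with a
#' zero total cannot be normalized and raise an error naming their barcodes.
#'
#' @param counts numeric genes x cells matrix of non-negative raw counts.
#' @return matrix of the same shape; every column sums to 1e6.
#' @export
#' @examples
#' cpm_normalize(matrix(c(2, 3, 5), ncol = 1,
#'                      dimnames = list(letters[1:3], "cell1")))
cpm_normalize <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero))
    stop("cell(s) with zero total count: ",
         paste(colnames(counts)[zero], collapse = ", "))
  sweep(counts, 2L, totals, "/") * 1e6
}

#' Verify annotated cell types by marker-gene clustering
#'
#' Hierarchically clusters cells on their marker-gene expression using
#' 1 - Pearson correlation as the distance and average linkage, cuts the
#' dendrogram at k = number of annotated cell types, and reports the adjusted
#' Rand index between the cut and the annotation, plus each marker's mean
#' expression in its own cell type versus all other cell types.
#'
#' @param norm normalized genes x cells matrix (e.g. from [cpm_normalize()]).
#' @param markers named list, cell type -> character vector of marker genes;
#'   markers absent from the matrix are flagged and skipped.
#' @param annotation data.frame with `barcode` and `cluster` columns covering
#'   the matrix's cells.
#' @return list: `ari`, `k`, `cut` (cluster assignment), `hclust`, `markers`
#'   (per-marker data.frame with own/other means and `present` flag),
#'   `absent_markers`.
#' @export
marker_cluster_verify <- function(norm, markers, annotation) {
  stopifnot(is.list(markers), length(markers) >= 2L)
  all_markers <- unlist(markers, use.names = FALSE)
  present <- all_markers[all_markers %in% rownames(norm)]
  absent <- setdiff(all_markers, present)
  if (!length(present)) stop("all marker genes absent from the matrix")

  ann <- annotation[match(colnames(norm), annotation$barcode), ]
  if (anyNA(ann$cluster)) stop("annotation missing for some barcodes")
  k <- length(unique(ann$cluster))

  sub <- norm[present, , drop = FALSE]
  d <- as.dist(1 - cor(sub))
  hc <- hclust(d, method = "average")
  cut <- cutree(hc, k = k)
  ari <- mclust::adjustedRandIndex(cut, ann$cluster)

  marker_tab <- do.call(rbind, lapply(names(markers), function(ct) {
    genes <- markers[[ct]]
    do.call(rbind, lapply(genes, function(g) {
      if (!g %in% rownames(norm))
        return(data.frame(cell_type = ct, gene = g, own_mean = NA_real_,
                          other_mean = NA_real_, present = FALSE))
      own <- if (!is.null(ann$stage_label) && ct %in% ann$stage_label)
        ann$stage_label == ct
      else ann$cluster == match(ct, names(markers))
      data.frame(cell_type = ct, gene = g,
                 own_mean = mean(norm[g, own]),
                 other_mean = mean(norm[g, !own]), present = TRUE)
    }))
  }))
  list(ari = ari, k = k, cut = cut, hclust = hc, markers = marker_tab,
       absent_markers = absent)
}

#' Median-normalized average expression per cluster
#'
#' Rescales each cell's counts so that its total equals the median of all
#' cell totals (the 10x Loupe browser convention), then averages the gene's
#' rescaled values within each annotated cluster, emitting clusters in
#' chronological stage order. When all cells share the same total this equals
#' the plain per-cluster mean of the raw counts.
#'
#' @param counts genes x cells raw count matrix.
#' @param annotation data.frame with `barcode`, `cluster` and (optionally)
#'   `stage_index` / `stage_label` columns.
#' @param gene a gene name present in the matrix.
#' @return a `cluster_profile`: named numeric vector of per-cluster
#'   median-normalized averages, ordered by stage index, with attribute
#'   `stage_labels`.
#' @export
#' @examples
#' m <- matrix(c(1, 99, 1, 99, 4, 196, 4, 196), nrow = 2,
#'             dimnames = list(c("g", "rest"), paste0("c", 1:4)))
#' ann <- data.frame(barcode = paste0("c", 1:4), cluster = c(1, 1, 2, 2))
#' median_normalized_average(m, ann, "g")
median_normalized_average <- function(counts, annotation, gene) {
  if (!gene %in% rownames(counts)) stop("gene absent from matrix: ", gene)
  ann <- annotation[match(colnames(counts), annotation$barcode), ]
  if (anyNA(ann$cluster)) stop("annotation missing for some barcodes")
  totals <- colSums(counts)
  if (any(totals == 0)) stop("cell(s) with zero total count")
  scaled <- counts[gene, ] * (median(totals) / totals)

  if (is.null(ann$stage_index)) ann$stage_index <- ann$cluster
  cl_order <- unique(ann$cluster[order(ann$stage_index)])
  prof <- vapply(cl_order, function(cl) mean(scaled[ann$cluster == cl]),
                 numeric(1))
  names(prof) <- as.character(cl_order)
  labels <- if (!is.null(ann$stage_label))
    vapply(cl_order, function(cl)
      as.character(ann$stage_label[ann$cluster == cl][1L]), character(1))
  else as.character(cl_order)
  structure(prof, stage_labels = labels, gene = gene,
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat("Stage profile for ", attr(x, "gene"), "\n", sep = "")
  df <- data.frame(stage = attr(x, "stage_labels"),
                   median_normalized_average = as.numeric(x))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Stage-profile report for a set of genes
#'
#' Computes the per-cluster median-normalized average profile for each gene
#' and names the stage of the peak cluster. A flat profile (max/mean < 1.5)
#' is flagged non-informative. Designed for side-by-side paralog comparisons.
#'
#' @inheritParams median_normalized_average
#' @param genes non-empty character vector of gene names.
#' @return list: `profiles` (named list of `cluster_profile`) and `table`
#'   (data.frame `gene`, `peak_stage`, `peak_value`, `informative`).
#' @export
stage_profile_report <- function(counts, annotation, genes) {
  if (!length(genes)) stop("gene list is empty")
  absent <- setdiff(genes, rownames(counts))
  if (length(absent)) stop("gene(s) absent from matrix: ",
                           paste(absent, collapse = ", "))
  profiles <- lapply(genes, function(g)
    median_normalized_average(counts, annotation, g))
  names(profiles) <- genes
  tab <- do.call(rbind, lapply(genes, function(g) {
    p <- profiles[[g]]
    peak <- which.max(p)
    data.frame(gene = g, peak_stage = attr(p, "stage_labels")[peak],
               peak_value = as.numeric(p[peak]),
               informative = mean(p) > 0 && max(p) / mean(p) >= 1.5,
               stringsAsFactors = FALSE)
  }))
  list(profiles = profiles, table = tab)
}
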