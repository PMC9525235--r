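# Single-cell UMI-count processing: global-scaling per-cell normalization
# (molecules per scale_factor UMIs), gene filtering on total counts,
# cluster-mean dot-plot matrices with per-gene max scaling,
# highest-homologue selection per gene family, and the summation-based
# mapping from peptide-assigned receptors to target cell clusters.

#' Construct a UMI matrix container
#'
#' @param counts genes x cells matrix of non-negative integer counts
#'   (base matrix or any Matrix class); must have row and column names.
#' @param cluster_of Named character vector mapping every cell to its
#'   cluster label.
#' @return An object of class `umi_matrix`.
#' @export
umi_matrix <- function(counts, cluster_of) {
  if (nrow(counts) > 0L && is.null(rownames(counts))) {
    stop("counts must have gene names")
  }
  stopifnot(!is.null(colnames(counts)),
            all(colnames(counts) %in% names(cluster_of)))
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts,
                 cluster_of = cluster_of[colnames(counts)]),
            class = "umi_matrix")
}

#' Drop genes with low total counts
#'
#' Removes genes whose total UMI count across all cells is below
#' `min_total`; cells are untouched.
#'
#' @param m A [umi_matrix()].
#' @param min_total Minimum total count to keep a gene (default 10, i.e.
#'   genes with totals less than 10 are removed).
#' @return A filtered `umi_matrix`.
#' @export
filter_genes <- function(m, min_total = 10) {
  stopifnot(inherits(m, "umi_matrix"))
  keep <- Matrix::rowSums(m$counts) >= min_total
  if (!any(keep)) warning("all genes removed by the total-count filter")
  umi_matrix(m$counts[keep, , drop = FALSE], m$cluster_of)
}

#' Global-scaling per-cell normalization
#'
#' Each cell's counts are divided by the cell's total (computed on the
#' matrix as given, i.e. before any gene filtering) and multiplied by
#' `scale_factor`, yielding molecules per `scale_factor` UMIs. Cells with
#' zero total are dropped with a warning.
#'
#' @param m A [umi_matrix()].
#' @param scale_factor Positive scale (e.g. 1000 or 10000).
#' @return A list of class `normalized_matrix`: `values` (genes x cells),
#'   `cluster_of`, `scale_factor`.
#' @export
normalize_cells <- function(m, scale_factor = 10000) {
  stopifnot(inherits(m, "umi_matrix"), scale_factor > 0)
  totals <- Matrix::colSums(m$counts)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " cell(s) with zero total counts dropped")
  }
  keep <- totals > 0
  counts <- m$counts[, keep, drop = FALSE]
  vals <- counts %*% Matrix::Diagonal(x = scale_factor / totals[keep])
  dimnames(vals) <- dimnames(counts)
  structure(list(values = vals, cluster_of = m$cluster_of[keep],
                 scale_factor = scale_factor),
            class = "normalized_matrix")
}

#' Per-cluster mean expression
#'
#' Arithmetic mean of normalized values over the member cells of each
#' cluster. Empty clusters (labels with no cells) are excluded with a
#' warning.
#'
#' @param nm A `normalized_matrix` from [normalize_cells()].
#' @param summary `"mean"` (default) or `"median"`.
#' @return An object of class `cluster_expression`: list with `genes`,
#'   `clusters`, `normalized_mean` (genes x clusters) and `scaled`
#'   (`NULL` until [scale_by_gene()]).
#' @export
cluster_means <- function(nm, summary = c("mean", "median")) {
  stopifnot(inherits(nm, "normalized_matrix"))
  summary <- match.arg(summary)
  cl <- factor(nm$cluster_of)
  empty <- setdiff(levels(cl), unique(as.character(cl)))
  if (length(empty)) warning("empty cluster(s) excluded: ", paste(empty, collapse = ", "))
  cl <- droplevels(cl)
  if (summary == "mean") {
    ind <- stats::model.matrix(~ cl - 1)
    colnames(ind) <- levels(cl)
    means <- as.matrix(nm$values %*% ind) %*% diag(1 / colSums(ind))
    colnames(means) <- levels(cl)
  } else {
    means <- sapply(levels(cl), function(k) {
      apply(as.matrix(nm$values[, cl == k, drop = FALSE]), 1, stats::median)
    })
  }
  structure(list(genes = rownames(nm$values), clusters = levels(cl),
                 normalized_mean = means, scaled = NULL),
            class = "cluster_expression")
}

#' Scale cluster means by gene maximum
#'
#' Divides each gene's row of cluster means by its maximum, mapping every
#' gene into \[0, 1\] (dot-plot size semantics). All-zero rows stay zero.
#'
#' @param ce A `cluster_expression` from [cluster_means()].
#' @return The same object with `scaled` filled.
#' @export
scale_by_gene <- function(ce) {
  stopifnot(inherits(ce, "cluster_expression"))
  mx <- apply(ce$normalized_mean, 1, max)
  mx[mx == 0] <- 1
  ce$scaled <- ce$normalized_mean / mx
  ce
}

#' Highest-expressed homologue per gene family
#'
#' For each family, selects the member gene with the greatest summed
#' normalized mean across clusters (ties broken by identifier order).
#' Families whose genes all dropped out of the matrix are reported in
#' `missing`, never silently discarded.
#'
#' @param ce A `cluster_expression`.
#' @param families Named list mapping family name to character vector of
#'   gene identifiers.
#' @return A list with `top` (named character vector, family -> gene) and
#'   `missing` (character vector of families with no surviving genes).
#' @export
top_homologue_per_family <- function(ce, families) {
  stopifnot(inherits(ce, "cluster_expression"))
  totals <- rowSums(ce$normalized_mean)
  missing <- character(0)
  top <- character(0)
  for (fam in names(families)) {
    genes <- intersect(families[[fam]], ce$genes)
    if (!length(genes)) {
      missing <- c(missing, fam)
      next
    }
    tt <- totals[genes]
    top[fam] <- genes[order(-tt, genes)][1]
  }
  list(top = top, missing = missing)
}

#' Peptide target-cell scores
#'
#' For each peptide, sums the normalized cluster-mean expression of all of
#' its assigned receptors, per cluster. Receptors absent from the
#' expression matrix are reported; peptides with no mapped receptor get a
#' zero row.
#'
#' @param assignments Data frame from [assign_receptors()] (`peptide_id`,
#'   `receptor_id`).
#' @param ce A `cluster_expression` whose genes include receptor ids.
#' @return A list with `targets` (peptides x clusters matrix) and
#'   `missing_receptors` (data frame of unmapped assignments).
#' @export
peptide_cell_targets <- function(assignments, ce) {
  stopifnot(inherits(ce, "cluster_expression"))
  peptides <- sort(unique(assignments$peptide_id))
  present <- assignments$receptor_id %in% ce$genes
  missing <- assignments[!present, , drop = FALSE]
  if (nrow(missing)) {
    warning(nrow(missing), " assigned receptor(s) absent from expression matrix")
  }
  targets <- matrix(0, nrow = length(peptides), ncol = length(ce$clusters),
                    dimnames = list(peptides, ce$clusters))
  ok <- assignments[present, , drop = FALSE]
  for (i in seq_len(nrow(ok))) {
    targets[ok$peptide_id[i], ] <- targets[ok$peptide_id[i], ] +
      ce$normalized_mean[ok$receptor_id[i], ]
  }
  list(targets = targets, missing_receptors = missing)
}
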