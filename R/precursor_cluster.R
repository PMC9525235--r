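# All-against-all local-alignment similarity network over precursor
# sequences, with Karlin-Altschul e-values in place of a search engine's
# statistic, and connected-component cluster extraction at an e-value
# cutoff (default 1e-5).

# Gapped Karlin-Altschul parameters for the supported scoring regime
.ka_params <- list(
  "BLOSUM62/11/1" = c(lambda = 0.267, K = 0.041)
)

.substitution_matrix <- function(name = "BLOSUM62") {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(err) FALSE)
  if (!ok || is.null(e[[name]])) stop("unknown substitution matrix: ", name)
  e[[name]]
}

.clean_seq <- function(x, alphabet) {
  chars <- strsplit(x, "")[[1]]
  bad <- !(chars %in% alphabet)
  if (any(bad)) {
    warning("non-standard residue(s) ", paste(unique(chars[bad]), collapse = ","),
            " treated as X")
    chars[bad] <- "X"
  }
  paste(chars, collapse = "")
}

#' Optimal local alignment score
#'
#' Smith-Waterman optimal local score with affine gaps (a gap of length L
#' costs `gap_open + L * gap_extend`), symmetric in its two sequences.
#' Non-standard residues are routed through the matrix's X wildcard row
#' with a warning.
#'
#' @param a,b Amino-acid sequences (non-empty character scalars).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (default 11/1, the
#'   common protein-search defaults).
#' @return Best local alignment score (matrix units; >= 0).
#' @export
local_align <- function(a, b, matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  stopifnot(nzchar(a), nzchar(b))
  mat <- .substitution_matrix(matrix)
  a <- .clean_seq(a, rownames(mat))
  b <- .clean_seq(b, rownames(mat))
  pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend,
                                      scoreOnly = TRUE)
  max(0, pa)
}

#' Karlin-Altschul e-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with gapped-regime constants for the
#' supported matrix/gap combination. Monotonically decreasing in `S` and
#' linear in the effective database size.
#'
#' @param score Alignment score (>= 0).
#' @param len_a Query length `m`.
#' @param len_b Subject length (used as the database size when
#'   `db_residues` is not given).
#' @param db_residues Total residues in the search database `n`.
#' @param matrix,gap_open,gap_extend The scoring regime; only
#'   BLOSUM62 with gaps 11/1 is parameterized (lambda = 0.267, K = 0.041).
#' @return Expected number of chance hits (e-value).
#' @export
estimate_evalue <- function(score, len_a, len_b = NULL, db_residues = NULL,
                            matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  stopifnot(all(score >= 0))
  key <- paste(matrix, gap_open, gap_extend, sep = "/")
  if (!key %in% names(.ka_params)) {
    stop("unsupported scoring regime ", key, "; supported: ",
         paste(names(.ka_params), collapse = ", "))
  }
  p <- .ka_params[[key]]
  n <- if (!is.null(db_residues)) db_residues else len_b
  if (is.null(n)) stop("provide len_b or db_residues")
  p[["K"]] * len_a * n * exp(-p[["lambda"]] * score)
}

#' Build the all-against-all similarity graph
#'
#' Aligns every unordered pair of precursors, computes the e-value with the
#' effective search space `m x (total database residues)`, and keeps edges
#' with e-value at or below `cutoff` (self-pairs excluded; edges stored
#' undirected with `id_a < id_b`).
#'
#' @param precursors Named character vector of precursor sequences.
#' @param cutoff E-value cutoff (default 1e-5).
#' @param matrix,gap_open,gap_extend Scoring regime, see [local_align()].
#' @return An object of class `cluster_graph`: list with `nodes`, `edges`
#'   (data frame: `id_a`, `id_b`, `score`, `evalue`), `cutoff`, and `graph`
#'   (an igraph object).
#' @export
build_graph <- function(precursors, cutoff = 1e-5, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  stopifnot(length(precursors) >= 1L, !is.null(names(precursors)))
  ids <- names(precursors)
  db_residues <- sum(nchar(precursors))
  pairs <- if (length(ids) >= 2L) utils::combn(seq_along(ids), 2L) else
    matrix(integer(0), nrow = 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    s <- local_align(precursors[[i]], precursors[[j]], matrix, gap_open, gap_extend)
    e <- estimate_evalue(s, nchar(precursors[[i]]), db_residues = db_residues,
                         matrix = matrix, gap_open = gap_open,
                         gap_extend = gap_extend)
    a <- ids[i]; b <- ids[j]
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    data.frame(id_a = a, id_b = b, score = s, evalue = e)
  })
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id_a = character(0), id_b = character(0),
               score = numeric(0), evalue = numeric(0))
  kept <- edges[edges$evalue <= cutoff, , drop = FALSE]
  g <- igraph::graph_from_data_frame(kept[c("id_a", "id_b")], directed = FALSE,
                                     vertices = data.frame(name = sort(ids)))
  structure(list(nodes = sort(ids), edges = kept, all_pairs = edges,
                 cutoff = cutoff, graph = g),
            class = "cluster_graph")
}

#' Extract clusters as connected components
#'
#' Network-visualization tools perform layout, not partitioning; cluster
#' membership here is the connected-component partition of the similarity
#' graph. Singletons are reported as size-1 clusters.
#'
#' @param graph A `cluster_graph` from [build_graph()].
#' @return Data frame with columns `id` and `cluster` (integer labels,
#'   assigned in order of each cluster's lexicographically smallest member).
#' @export
components <- function(graph) {
  stopifnot(inherits(graph, "cluster_graph"))
  comp <- igraph::components(graph$graph)
  membership <- comp$membership[order(names(comp$membership))]
  # relabel deterministically by smallest member id
  first_seen <- !duplicated(membership)
  relabel <- stats::setNames(seq_len(sum(first_seen)), membership[first_seen])
  data.frame(id = names(membership),
             cluster = unname(relabel[as.character(membership)]),
             row.names = NULL)
}
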