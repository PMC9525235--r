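# Readers and writers for the plain-text formats the pipeline consumes and
# emits: FASTA (via Biostrings), TSV tables, MatrixMarket counts.

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a table as TSV
#'
#' @param df A data frame.
#' @param path Output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#'
#' @param path Input file.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a peptide-spectrum-match table
#'
#' Expected columns: `sequence`, `modifications` (semicolon-separated tokens
#' among `amidated`, `pyroglu`, `ox:<pos>` with 0-based positions; empty for
#' none), `precursor_id`, `score`, and optionally `engine`.
#'
#' @param path TSV file.
#' @return A `psm_table` data frame with logical `c_amidated`/`n_pyroglu`
#'   columns and a character `oxidized_positions` column (comma-separated
#'   0-based indices).
#' @export
read_psm_table <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("sequence", "modifications", "precursor_id", "score") %in% names(df)))
  mods <- strsplit(ifelse(is.na(df$modifications), "", df$modifications), ";", fixed = TRUE)
  df$c_amidated <- vapply(mods, function(m) "amidated" %in% m, logical(1))
  df$n_pyroglu <- vapply(mods, function(m) "pyroglu" %in% m, logical(1))
  df$oxidized_positions <- vapply(mods, function(m) {
    ox <- grep("^ox:", m, value = TRUE)
    paste(sub("^ox:", "", ox), collapse = ",")
  }, character(1))
  if (is.null(df$engine)) df$engine <- "unknown"
  df
}

#' Write a peptide-spectrum-match table
#'
#' Inverse of [read_psm_table()].
#'
#' @param df A psm table data frame.
#' @param path Output TSV.
#' @export
write_psm_table <- function(df, path) {
  mods <- mapply(function(am, pg, ox) {
    toks <- c(if (isTRUE(am)) "amidated", if (isTRUE(pg)) "pyroglu",
              if (nzchar(ox)) paste0("ox:", strsplit(ox, ",")[[1]]))
    paste(toks, collapse = ";")
  }, df$c_amidated, df$n_pyroglu,
     if (is.null(df$oxidized_positions)) rep("", nrow(df)) else df$oxidized_positions)
  out <- data.frame(sequence = df$sequence, modifications = unlist(mods),
                    precursor_id = df$precursor_id, score = df$score,
                    engine = if (is.null(df$engine)) "unknown" else df$engine)
  write_tsv(out, path)
}

#' Read a protein-domain hit table
#'
#' Accepts either a plain TSV with columns `protein_id`, `motif_accession`,
#' `evalue`, or HMMER-style whitespace-delimited tabular output (`--tblout`)
#' with `#` comment lines, from which target name, query accession and
#' full-sequence e-value are taken.
#'
#' @param path Input file.
#' @return Data frame with columns `protein_id`, `motif_accession`, `evalue`.
#' @export
read_domain_hits <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) {
    df <- read_tsv(path)
    stopifnot(all(c("protein_id", "motif_accession", "evalue") %in% names(df)))
    return(df[c("protein_id", "motif_accession", "evalue")])
  }
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(protein_id = character(0), motif_accession = character(0),
                      evalue = numeric(0)))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  data.frame(
    protein_id = vapply(fields, `[`, character(1), 1L),
    motif_accession = vapply(fields, `[`, character(1), 4L),
    evalue = as.numeric(vapply(fields, `[`, character(1), 5L))
  )
}

#' Write / read peptide lists
#'
#' Peptidoform lists are stored as TSV with columns `peptide_id`,
#' `sequence`, `c_amidated`, `n_pyroglu`, `oxidized_positions` (0-based,
#' comma-separated).
#'
#' @param peptides Named list of [peptidoform()] objects.
#' @param path TSV file.
#' @export
write_peptides <- function(peptides, path) {
  df <- data.frame(
    peptide_id = names(peptides),
    sequence = vapply(peptides, function(p) p$sequence, character(1)),
    c_amidated = vapply(peptides, function(p) p$c_amidated, logical(1)),
    n_pyroglu = vapply(peptides, function(p) p$n_pyroglu, logical(1)),
    oxidized_positions = vapply(peptides, function(p) {
      paste(p$oxidized_positions, collapse = ",")
    }, character(1)))
  write_tsv(df, path)
}

#' @rdname write_peptides
#' @return `read_peptides` returns a named list of [peptidoform()]s.
#' @export
read_peptides <- function(path) {
  df <- read_tsv(path)
  out <- lapply(seq_len(nrow(df)), function(i) {
    ox <- df$oxidized_positions[i]
    peptidoform(df$sequence[i], c_amidated = df$c_amidated[i],
                n_pyroglu = df$n_pyroglu[i],
                oxidized_positions = if (is.na(ox) || !nzchar(ox)) integer(0)
                                     else as.integer(strsplit(as.character(ox), ",")[[1]]))
  })
  stats::setNames(out, df$peptide_id)
}

#' Write / read receptor models
#'
#' Receptor sequences go to FASTA; transmembrane-segment annotations to a
#' TSV with columns `receptor_id`, `seg_index`, `start`, `end` (0-based
#' half-open).
#'
#' @param receptors Named list of [receptor_model()] objects.
#' @param fasta_path,tm_path Output files.
#' @export
write_receptors <- function(receptors, fasta_path, tm_path) {
  seqs <- vapply(receptors, function(r) r$sequence, character(1))
  write_fasta(seqs, fasta_path)
  tm <- do.call(rbind, lapply(receptors, function(r) {
    data.frame(receptor_id = r$receptor_id,
               seg_index = seq_len(nrow(r$tm_segments)),
               start = r$tm_segments$start, end = r$tm_segments$end)
  }))
  rownames(tm) <- NULL
  write_tsv(tm, tm_path)
}

#' @rdname write_receptors
#' @return `read_receptors` returns a named list of [receptor_model()]s.
#' @export
read_receptors <- function(fasta_path, tm_path) {
  seqs <- read_fasta(fasta_path)
  tm <- read_tsv(tm_path)
  out <- lapply(names(seqs), function(id) {
    segs <- tm[tm$receptor_id == id, c("start", "end"), drop = FALSE]
    receptor_model(id, seqs[[id]], segs)
  })
  stats::setNames(out, names(seqs))
}

#' Read a sparse UMI count matrix
#'
#' @param mtx_path MatrixMarket file (genes x cells).
#' @param genes_path,cells_path One-column files of gene / cell identifiers.
#' @param clusters_path TSV with columns `cell`, `cluster`.
#' @return A `umi_matrix`: list with `counts` (dgCMatrix, genes x cells) and
#'   `cluster_of` (named character vector over cells).
#' @export
read_umi_matrix <- function(mtx_path, genes_path, cells_path, clusters_path) {
  counts <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  rownames(counts) <- readLines(genes_path)
  colnames(counts) <- readLines(cells_path)
  cl <- read_tsv(clusters_path)
  cluster_of <- stats::setNames(as.character(cl$cluster), cl$cell)
  umi_matrix(counts, cluster_of)
}

#' Write a sparse UMI count matrix
#'
#' @param m A `umi_matrix` (see [umi_matrix()]).
#' @param dir Output directory; files `counts.mtx`, `genes.tsv`, `cells.tsv`,
#'   `clusters.tsv` are written there.
#' @export
write_umi_matrix <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "counts.mtx"))
  writeLines(rownames(m$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(m$counts), file.path(dir, "cells.tsv"))
  write_tsv(data.frame(cell = colnames(m$counts),
                       cluster = unname(m$cluster_of[colnames(m$counts)])),
            file.path(dir, "clusters.tsv"))
  invisible(dir)
}
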