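# Precursor annotation: locate mature peptides inside precursor sequences,
# classify the two-residue cleavage sites on each side (dibasic K/R vs
# acidic D/E), detect the glycine amide donor that follows amidated
# peptides, and build logo-ready cleavage-context frequency matrices.
#
# Coordinates are 0-based, half-open throughout.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Map peptides onto a precursor sequence
#'
#' Reports every exact (possibly overlapping) occurrence of each peptide
#' sequence in the precursor. Peptides absent from the precursor are
#' collected in a `misses` vector rather than silently dropped.
#'
#' @param precursor Character scalar, the precursor amino-acid sequence.
#' @param peptides Character vector of peptide sequences, or a list of
#'   [peptidoform()] objects.
#' @return A list with `spans` (data frame: `peptide`, `start`, `end`;
#'   0-based half-open) and `misses` (character vector).
#' @export
map_peptides <- function(precursor, peptides) {
  if (is.list(peptides)) {
    peptides <- vapply(peptides, function(p) p$sequence, character(1))
  }
  stopifnot(length(peptides) >= 1L)
  subject <- Biostrings::AAString(precursor)
  rows <- lapply(unique(peptides), function(pep) {
    m <- Biostrings::matchPattern(pep, subject)
    if (length(m) == 0L) return(NULL)
    data.frame(peptide = pep,
               start = Biostrings::start(m) - 1L,
               end = Biostrings::end(m))
  })
  spans <- do.call(rbind, rows)
  if (is.null(spans)) {
    spans <- data.frame(peptide = character(0), start = integer(0), end = integer(0))
  }
  list(spans = spans, misses = setdiff(unique(peptides), spans$peptide))
}

#' Build a precursor annotation
#'
#' @param precursor_id Identifier.
#' @param sequence Precursor amino-acid sequence.
#' @param peptides Character vector of mature peptide sequences (or list of
#'   [peptidoform()]s) to locate in the precursor.
#' @param amidated Logical vector parallel to `peptides` (recycled);
#'   whether each peptide is C-terminally amidated.
#' @param signal_peptide Optional length-2 integer, 0-based half-open
#'   signal-peptide interval (consumed as input annotation, not predicted).
#' @return An object of class `precursor_annotation` with `peptide_spans`
#'   (data frame incl. `amidated` column), `misses`, and empty
#'   `cleavage_sites` to be filled by [classify_sites()].
#' @export
precursor_annotation <- function(precursor_id, sequence, peptides,
                                 amidated = FALSE, signal_peptide = NULL) {
  mapped <- map_peptides(sequence, peptides)
  if (is.list(peptides) && !is.data.frame(peptides)) {
    pep_seqs <- vapply(peptides, function(p) p$sequence, character(1))
    am <- vapply(peptides, function(p) isTRUE(p$c_amidated), logical(1))
  } else {
    pep_seqs <- peptides
    am <- rep_len(amidated, length(peptides))
  }
  amide_of <- tapply(am, pep_seqs, any)
  spans <- mapped$spans
  spans$amidated <- if (nrow(spans)) unname(amide_of[spans$peptide]) else logical(0)
  structure(list(
    precursor_id = precursor_id,
    sequence = sequence,
    signal_peptide = if (is.null(signal_peptide)) NULL else as.integer(signal_peptide),
    peptide_spans = spans,
    misses = mapped$misses,
    cleavage_sites = NULL
  ), class = "precursor_annotation")
}

.site_class <- function(site) {
  if (is.na(site) || nchar(site) < 2L) return(NA_character_)
  r <- strsplit(site, "")[[1]]
  basic <- r %in% c("K", "R")
  acidic <- r %in% c("D", "E")
  if (all(basic)) "basic"
  else if (all(acidic)) "acidic"
  else if (any(basic) && any(acidic)) "mixed"
  else "other"
}

#' Classify cleavage sites around mapped peptides
#'
#' For each peptide span, extracts the two precursor residues immediately
#' preceding the span (N-terminal site) and the two immediately following
#' it (C-terminal site), skipping one glycine amide donor after amidated
#' peptides. Sites are classed `basic` (both K/R), `acidic` (both D/E),
#' `mixed` (one of each), or `other`. Spans abutting a precursor terminus
#' get an absent (`NA`) site on that side, never a fabricated one.
#'
#' @param ann A [precursor_annotation()].
#' @return The annotation with `cleavage_sites` filled: a data frame with
#'   one row per span and side (`side`, `position`, `site_residues`, `cls`).
#' @export
classify_sites <- function(ann) {
  stopifnot(inherits(ann, "precursor_annotation"))
  seqlen <- nchar(ann$sequence)
  spans <- ann$peptide_spans
  rows <- lapply(seq_len(nrow(spans)), function(i) {
    s <- spans$start[i]
    e <- spans$end[i]
    # N-terminal site: residues [s-2, s)
    n_site <- if (s >= 2L) substr(ann$sequence, s - 1L, s) else NA_character_
    # C-terminal site: residues after the span; amide donor G is linker,
    # not site, so it is skipped when the peptide is amidated
    cstart <- e
    if (isTRUE(spans$amidated[i]) && cstart < seqlen &&
        substr(ann$sequence, cstart + 1L, cstart + 1L) == "G") {
      cstart <- cstart + 1L
    }
    c_site <- if (cstart + 2L <= seqlen) {
      substr(ann$sequence, cstart + 1L, cstart + 2L)
    } else NA_character_
    data.frame(
      peptide = spans$peptide[i],
      side = c("n_terminal", "c_terminal"),
      position = c(s, cstart),
      site_residues = c(n_site, c_site),
      cls = c(.site_class(n_site), .site_class(c_site))
    )
  })
  ann$cleavage_sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide = character(0), side = character(0), position = integer(0),
               site_residues = character(0), cls = character(0))
  ann
}

#' Detect glycine amide donors
#'
#' Flags each span whose following precursor residue is G (the amide
#' donor). Amidated peptides lacking a following G are collected into an
#' inconsistency report.
#'
#' @param ann A [precursor_annotation()].
#' @return A list with `donor` (logical vector over spans) and
#'   `inconsistencies` (data frame of amidated spans with no donor G).
#' @export
detect_amide_donor <- function(ann) {
  stopifnot(inherits(ann, "precursor_annotation"))
  spans <- ann$peptide_spans
  seqlen <- nchar(ann$sequence)
  donor <- vapply(seq_len(nrow(spans)), function(i) {
    e <- spans$end[i]
    e < seqlen && substr(ann$sequence, e + 1L, e + 1L) == "G"
  }, logical(1))
  bad <- spans$amidated & !donor
  list(donor = donor,
       inconsistencies = spans[bad, , drop = FALSE])
}

#' Detect N-terminal pyroglutamation
#'
#' Annotation pass-through: flag is true iff the first residue is Q or E and
#' the identification carried the pyroGlu mass delta.
#'
#' @param peptides List of [peptidoform()] objects.
#' @return Logical vector.
#' @export
detect_pyroglu <- function(peptides) {
  vapply(peptides, function(p) {
    isTRUE(p$n_pyroglu) && substr(p$sequence, 1, 1) %in% c("Q", "E")
  }, logical(1))
}

.context_matrix <- function(windows, positions) {
  counts <- matrix(0L, nrow = length(.AA20), ncol = length(positions),
                   dimnames = list(.AA20, positions))
  for (w in windows) {
    chars <- strsplit(w, "")[[1]]
    for (j in seq_along(chars)) {
      if (chars[j] %in% .AA20) counts[chars[j], j] <- counts[chars[j], j] + 1L
    }
  }
  totals <- colSums(counts)
  freqs <- sweep(counts, 2, pmax(totals, 1L), "/")
  structure(list(positions = positions, counts = counts, frequencies = freqs,
                 n_windows = length(windows)),
            class = "context_matrix")
}

#' Cleavage-context matrices
#'
#' For every cleavage junction across the annotations, extracts a window of
#' `flank_len + site_len` precursor-side residues: right-aligned at the
#' junction for N-terminal sites (positions `-(flank+site) .. -1`) and
#' left-aligned for C-terminal sites (positions `+1 .. +(site+flank)`); the
#' glycine amide donor after an amidated peptide is skipped, consistent
#' with [classify_sites()]. Window positions falling outside the precursor
#' are padded with `-` and excluded from the frequencies, so every column
#' with at least one observation sums to 1.
#'
#' @param annotations List of [precursor_annotation()] objects (sites need
#'   not be classified beforehand).
#' @param site_len Residues in the site proper (default 2).
#' @param flank_len Flanking residues beyond the site (default 6).
#' @return A list with `n_terminal` and `c_terminal` `context_matrix`
#'   objects (20 x positions counts and frequencies, logo-ready).
#' @export
cleavage_context <- function(annotations, site_len = 2L, flank_len = 6L) {
  stopifnot(site_len >= 0L, flank_len >= 0L)
  w <- site_len + flank_len
  n_windows <- character(0)
  c_windows <- character(0)
  for (ann in annotations) {
    seqlen <- nchar(ann$sequence)
    spans <- ann$peptide_spans
    for (i in seq_len(nrow(spans))) {
      s <- spans$start[i]
      e <- spans$end[i]
      if (isTRUE(spans$amidated[i]) && e < seqlen &&
          substr(ann$sequence, e + 1L, e + 1L) == "G") {
        e <- e + 1L
      }
      if (s > 0L) {
        lo <- max(0L, s - w)
        win <- substr(ann$sequence, lo + 1L, s)
        n_windows <- c(n_windows,
                       paste0(strrep("-", w - nchar(win)), win))
      }
      if (e < seqlen) {
        hi <- min(seqlen, e + w)
        win <- substr(ann$sequence, e + 1L, hi)
        c_windows <- c(c_windows,
                       paste0(win, strrep("-", w - nchar(win))))
      }
    }
  }
  if (w == 0L) {
    n_pos <- c_pos <- character(0)
  } else {
    n_pos <- as.character(seq(-w, -1L))
    c_pos <- paste0("+", seq_len(w))
  }
  list(n_terminal = .context_matrix(n_windows, n_pos),
       c_terminal = .context_matrix(c_windows, c_pos))
}

#' Write a context matrix as a logo-ready frequency table
#'
#' @param cm A `context_matrix` from [cleavage_context()].
#' @param path Output TSV (positions as rows, 20 residues as columns).
#' @export
write_context_matrix <- function(cm, path) {
  df <- as.data.frame(t(cm$frequencies))
  df <- cbind(position = rownames(df), df)
  write_tsv(df, path)
}
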