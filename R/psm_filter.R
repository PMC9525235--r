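# Post-search filtering of peptide-spectrum matches down to a curated
# amidated-peptide list: (1) drop peptides whose precursor carries a
# non-neuropeptide protein-domain hit below a strict e-value cutoff,
# (2) keep C-terminally amidated identifications only, (3) keep the top
# scoring identification per precursor.
#
# PSM tables are plain data frames with columns: sequence, c_amidated,
# n_pyroglu, oxidized_positions, precursor_id, score, engine.

#' Filtering configuration
#'
#' @param allowed_motifs Character vector of motif accessions regarded as
#'   neuropeptide-related, hence exempt from the domain exclusion. The
#'   default (empty) excludes on any hit.
#' @param exclusion_evalue Positive e-value cutoff; a precursor is a
#'   contaminant when it has a disallowed motif hit at or below it.
#' @param require_amidation Keep C-terminally amidated identifications only.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(allowed_motifs = character(0),
                          exclusion_evalue = 1e-10,
                          require_amidation = TRUE) {
  stopifnot(exclusion_evalue > 0)
  structure(list(allowed_motifs = allowed_motifs,
                 exclusion_evalue = exclusion_evalue,
                 require_amidation = isTRUE(require_amidation)),
            class = "filter_config")
}

#' Remove records whose precursor has disallowed domain hits
#'
#' A record is removed iff its precursor has at least one hit whose motif is
#' not in `cfg$allowed_motifs` with e-value at or below
#' `cfg$exclusion_evalue`. Precursors with no hits survive.
#'
#' @param records PSM data frame.
#' @param hits Domain-hit data frame (`protein_id`, `motif_accession`,
#'   `evalue`), e.g. from [read_domain_hits()].
#' @param cfg A [filter_config()].
#' @return The surviving subset of `records`.
#' @export
exclude_by_domains <- function(records, hits, cfg = filter_config()) {
  if (nrow(records) == 0L || is.null(hits) || nrow(hits) == 0L) return(records)
  bad <- !(hits$motif_accession %in% cfg$allowed_motifs) &
    hits$evalue <= cfg$exclusion_evalue
  contaminants <- unique(hits$protein_id[bad])
  records[!(records$precursor_id %in% contaminants), , drop = FALSE]
}

#' Keep C-terminally amidated identifications
#'
#' @param records PSM data frame.
#' @return Subset of `records` with `c_amidated == TRUE`.
#' @export
retain_amidated <- function(records) {
  records[records$c_amidated, , drop = FALSE]
}

#' Top-scoring representative per precursor
#'
#' For each `precursor_id`, keeps the highest-scoring record. Score ties
#' are broken toward the longer peptide (to avoid artifactual truncation
#' products), then lexicographic sequence order.
#'
#' @param records PSM data frame.
#' @return One record per precursor, ordered by precursor id.
#' @export
select_top_per_precursor <- function(records) {
  if (nrow(records) == 0L) return(records)
  ord <- order(records$precursor_id,
               -records$score,
               -nchar(records$sequence),
               records$sequence)
  sorted <- records[ord, , drop = FALSE]
  sorted[!duplicated(sorted$precursor_id), , drop = FALSE]
}

#' Run the full post-search filter
#'
#' Composes [exclude_by_domains()], [retain_amidated()] (skipped when
#' `cfg$require_amidation` is `FALSE`) and [select_top_per_precursor()], in
#' that order. The composition is idempotent.
#'
#' @param records PSM data frame.
#' @param hits Domain-hit data frame (may be `NULL`).
#' @param cfg A [filter_config()].
#' @return Curated PSM data frame, one record per surviving precursor.
#' @export
run_filter <- function(records, hits = NULL, cfg = filter_config()) {
  out <- exclude_by_domains(records, hits, cfg)
  if (cfg$require_amidation) out <- retain_amidated(out)
  select_top_per_precursor(out)
}
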