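# Seeded synthetic-data generators emulating every upstream input of the
# pipeline, with ground-truth manifests for parameter-recovery tests:
# precursor architectures (signal peptide, repeated peptide copies flanked
# by dibasic/acidic cleavage sites, glycine amide donors), PSM tables with
# decoys and domain-hit contaminants, compound-protein-interaction tables
# with a planted bilinear interaction rule that is learnable in the
# outer-product feature space, and clustered negative-binomial UMI count
# matrices with planted marker genes.
#
# Each generator draws from its own sub-stream derived from the master
# seed, so stages are reproducible when re-run independently; the same
# configuration yields byte-identical outputs.

.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.HYDROPHOBIC <- c("A", "I", "L", "V", "F", "M", "W")
.NEUTRAL <- setdiff(.AA, c("K", "R", "D", "E", "G"))

#' Generator configuration
#'
#' Bundles all knobs of the synthetic-data generators. Defaults are the
#' study conditions exercised by the test-suite: 200 precursors with 1-4
#' peptide copies each, 70% dibasic / 30% acidic cleavage sites, 80%
#' amidated peptides, a quarter contaminant precursors in the PSM table, a
#' 100 x 100 peptide-receptor grid with 600 planted interactions and no
#' label noise, and a 2,000-gene x 5,000-cell count matrix over 10
#' clusters with 8-fold elevated markers.
#'
#' @param seed Master integer seed; all generator streams derive from it.
#' @param n_precursors Number of precursors to simulate.
#' @param copies_range Length-2 integer range of peptide copies per
#'   precursor.
#' @param peptide_len_range Length-2 range of mature-peptide lengths.
#' @param basic_site_fraction Probability that a cleavage site is dibasic
#'   (K/R pairs) rather than acidic (D/E pairs).
#' @param amidated_fraction Probability that a precursor's peptide is
#'   C-terminally amidated (and hence followed by a glycine donor).
#' @param psm_decoy_fraction Contaminant precursors in the PSM table, as a
#'   fraction of `n_precursors`.
#' @param cpi List: `n_peptides`, `n_receptors`, `n_distractors` (receptors
#'   with fewer than 7 TM segments), `n_positives`, `rule_rank`,
#'   `rule_strength`, `label_noise`.
#' @param umi List: `n_genes`, `n_cells`, `n_clusters`, `marker_fold`,
#'   `dispersion` (negative-binomial size parameter).
#' @return A list of class `gen_config`.
#' @export
gen_config <- function(seed = 1L,
                       n_precursors = 200L,
                       copies_range = c(1L, 4L),
                       peptide_len_range = c(6L, 16L),
                       basic_site_fraction = 0.7,
                       amidated_fraction = 0.8,
                       psm_decoy_fraction = 0.25,
                       cpi = list(),
                       umi = list()) {
  stopifnot(basic_site_fraction >= 0, basic_site_fraction <= 1,
            amidated_fraction >= 0, amidated_fraction <= 1,
            psm_decoy_fraction >= 0, psm_decoy_fraction <= 1)
  cpi_def <- list(n_peptides = 100L, n_receptors = 100L, n_distractors = 10L,
                  n_positives = 600L, rule_rank = 3L, rule_strength = 1,
                  label_noise = 0)
  umi_def <- list(n_genes = 2000L, n_cells = 5000L, n_clusters = 10L,
                  marker_fold = 8, dispersion = 2)
  cpi_def[names(cpi)] <- cpi
  umi_def[names(umi)] <- umi
  stopifnot(cpi_def$label_noise >= 0, cpi_def$label_noise <= 1)
  structure(list(seed = as.integer(seed),
                 n_precursors = as.integer(n_precursors),
                 copies_range = as.integer(copies_range),
                 peptide_len_range = as.integer(peptide_len_range),
                 basic_site_fraction = basic_site_fraction,
                 amidated_fraction = amidated_fraction,
                 psm_decoy_fraction = psm_decoy_fraction,
                 cpi = cpi_def, umi = umi_def),
            class = "gen_config")
}

.rand_seq <- function(n, alphabet = .AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Mature-peptide sequence with a mild aromatic C-terminal bias, echoing the
# aromatic amidated C-termini typical of short neuropeptides.
.rand_peptide <- function(len) {
  body <- sample(.AA, len - 1L, replace = TRUE)
  tail <- sample(c("W", "Y", "F", sample(.AA, 1)), 1L)
  paste(c(body, tail), collapse = "")
}

.rand_site <- function(basic) {
  if (basic) paste(sample(c("K", "R"), 2L, replace = TRUE), collapse = "")
  else paste(sample(c("D", "E"), 2L, replace = TRUE), collapse = "")
}

# Substitute n_sub random positions with random canonical residues.
.mutate_seq <- function(s, n_sub, alphabet = .AA) {
  chars <- strsplit(s, "")[[1]]
  pos <- sample(length(chars), min(n_sub, length(chars)))
  chars[pos] <- sample(alphabet, length(pos), replace = TRUE)
  paste(chars, collapse = "")
}

#' Generate synthetic neuropeptide precursors
#'
#' Each precursor is an N-terminal hydrophobic signal stretch followed by
#' 1 or more copies of a single mature peptide, every copy flanked by a
#' two-residue cleavage site drawn dibasic with probability
#' `basic_site_fraction` (else acidic), with a glycine amide donor inserted
#' after amidated peptides, and a short neutral C-terminal tail. Peptides
#' are redrawn if assembly creates spurious occurrences, so the manifest's
#' copy counts are exact.
#'
#' @param cfg A [gen_config()].
#' @return List with `fasta` (named character vector of precursor
#'   sequences) and `manifest`: `peptides` (one row per planted copy:
#'   `precursor_id`, `peptide`, `amidated`, `start`, `end`, `n_site`,
#'   `c_site`, `n_class`, `c_class`, `donor`) and `signal_peptides`.
#' @export
gen_precursors <- function(cfg = gen_config()) {
  with_seed(sub_seed(cfg$seed, "precursors"), {
    fasta <- character(0)
    rows <- list()
    sig_rows <- list()
    used_peptides <- character(0)
    for (i in seq_len(cfg$n_precursors)) {
      id <- sprintf("prec%04d", i)
      copies <- sample(seq(cfg$copies_range[1], cfg$copies_range[2]), 1L)
      amidated <- stats::runif(1) < cfg$amidated_fraction
      for (try in 1:100) {
        len <- sample(seq(cfg$peptide_len_range[1], cfg$peptide_len_range[2]), 1L)
        pep <- .rand_peptide(len)
        if (pep %in% used_peptides) next
        signal <- paste0("M", .rand_seq(18L, .HYDROPHOBIC))
        parts <- signal
        copy_rows <- list()
        pos <- nchar(signal)
        ok_sites <- TRUE
        for (k in seq_len(copies)) {
          n_basic <- stats::runif(1) < cfg$basic_site_fraction
          c_basic <- stats::runif(1) < cfg$basic_site_fraction
          n_site <- .rand_site(n_basic)
          c_site <- .rand_site(c_basic)
          chunk <- paste0(n_site, pep, if (amidated) "G", c_site)
          start <- pos + 2L
          end <- start + len
          copy_rows[[k]] <- data.frame(
            precursor_id = id, peptide = pep, amidated = amidated,
            start = start, end = end, n_site = n_site, c_site = c_site,
            n_class = if (n_basic) "basic" else "acidic",
            c_class = if (c_basic) "basic" else "acidic",
            donor = amidated)
          parts <- c(parts, chunk)
          pos <- pos + nchar(chunk)
        }
        tail_seq <- .rand_seq(3L, .NEUTRAL)
        full <- paste0(paste(parts, collapse = ""), tail_seq)
        hits <- map_peptides(full, pep)$spans
        if (nrow(hits) == copies && ok_sites) {
          fasta[id] <- full
          rows <- c(rows, copy_rows)
          sig_rows[[id]] <- data.frame(precursor_id = id, start = 0L,
                                       end = nchar(signal))
          used_peptides <- c(used_peptides, pep)
          break
        }
      }
    }
    manifest <- list(peptides = do.call(rbind, rows),
                     signal_peptides = do.call(rbind, sig_rows))
    rownames(manifest$peptides) <- NULL
    rownames(manifest$signal_peptides) <- NULL
    list(fasta = fasta, manifest = manifest)
  })
}

#' Verify a precursor manifest against emitted sequences
#'
#' Independent checker: every manifest claim (span subsequence identity,
#' donor glycine, site residues at the stated offsets and their classes) is
#' re-derived from the FASTA sequences.
#'
#' @param fasta Named character vector of precursor sequences.
#' @param manifest The `manifest` element of [gen_precursors()].
#' @return `TRUE` invisibly; stops at the first violated claim.
#' @export
verify_precursor_truth <- function(fasta, manifest) {
  pep <- manifest$peptides
  for (i in seq_len(nrow(pep))) {
    s <- fasta[[pep$precursor_id[i]]]
    sub <- substr(s, pep$start[i] + 1L, pep$end[i])
    if (sub != pep$peptide[i]) stop("span mismatch at row ", i)
    if (pep$donor[i]) {
      if (substr(s, pep$end[i] + 1L, pep$end[i] + 1L) != "G")
        stop("missing donor G at row ", i)
    }
    nsite <- substr(s, pep$start[i] - 1L, pep$start[i])
    if (nsite != pep$n_site[i]) stop("n_site mismatch at row ", i)
    coff <- pep$end[i] + as.integer(pep$donor[i])
    csite <- substr(s, coff + 1L, coff + 2L)
    if (csite != pep$c_site[i]) stop("c_site mismatch at row ", i)
    if (.site_class(nsite) != pep$n_class[i]) stop("n_class mismatch at row ", i)
    if (.site_class(csite) != pep$c_class[i]) stop("c_class mismatch at row ", i)
  }
  invisible(TRUE)
}

#' Generate a synthetic PSM table with domain-hit contaminants
#'
#' For every planted precursor the table carries one top-scoring amidated
#' record (the truth the filter must recover), one lower-scoring amidated
#' truncation variant and two non-amidated decoy records. Contaminant
#' precursors (a `psm_decoy_fraction` of the planted count) contribute
#' high-scoring amidated records but carry a disallowed protein-domain hit
#' below the exclusion cutoff; planted precursors receive only allowed-motif
#' hits or disallowed hits above the cutoff.
#'
#' @param cfg A [gen_config()].
#' @param manifest Manifest from [gen_precursors()].
#' @return List with `psms` (PSM data frame), `hits` (domain-hit data
#'   frame), `allowed_motifs`, and `truth` (the expected output of
#'   [run_filter()], ordered by precursor id).
#' @export
gen_psm_table <- function(cfg, manifest) {
  with_seed(sub_seed(cfg$seed, "psms"), {
    per_prec <- unique(manifest$peptides[c("precursor_id", "peptide", "amidated")])
    # filter truth only concerns amidated peptides
    recs <- list()
    hit_rows <- list()
    truth_rows <- list()
    allowed <- c("NPHORM1", "NPHORM2")
    for (i in seq_len(nrow(per_prec))) {
      id <- per_prec$precursor_id[i]
      pep <- per_prec$peptide[i]
      top_score <- stats::runif(1, 70, 100)
      low <- stats::runif(3, 10, 69)
      trunc <- substr(pep, 2L, nchar(pep))
      recs[[length(recs) + 1L]] <- data.frame(
        sequence = c(pep, trunc, pep, trunc),
        # non-amidated planted peptides are only ever seen as free acids
        c_amidated = if (per_prec$amidated[i]) c(TRUE, TRUE, FALSE, FALSE)
                     else rep(FALSE, 4L),
        n_pyroglu = FALSE,
        oxidized_positions = "",
        precursor_id = id,
        score = c(top_score, low),
        engine = "synthetic")
      if (per_prec$amidated[i]) {
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          precursor_id = id, sequence = pep, score = top_score)
      }
      # benign hits: allowed motif below cutoff, disallowed above cutoff
      if (stats::runif(1) < 0.5) {
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          protein_id = id, motif_accession = sample(allowed, 1L),
          evalue = 10^stats::runif(1, -30, -11))
      }
      if (stats::runif(1) < 0.3) {
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          protein_id = id, motif_accession = "JUNKDOM",
          evalue = 10^stats::runif(1, -8, -3))
      }
    }
    n_contam <- round(cfg$psm_decoy_fraction * cfg$n_precursors)
    for (j in seq_len(n_contam)) {
      id <- sprintf("contam%04d", j)
      pep <- .rand_peptide(sample(8:14, 1L))
      trunc <- substr(pep, 2L, nchar(pep))
      recs[[length(recs) + 1L]] <- data.frame(
        sequence = c(pep, trunc, pep, trunc),
        c_amidated = c(TRUE, TRUE, FALSE, FALSE),
        n_pyroglu = FALSE,
        oxidized_positions = "",
        precursor_id = id,
        score = c(stats::runif(1, 70, 100), stats::runif(3, 10, 69)),
        engine = "synthetic")
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        protein_id = id, motif_accession = "JUNKDOM",
        evalue = 10^stats::runif(1, -30, -10.5))
    }
    psms <- do.call(rbind, recs)
    rownames(psms) <- NULL
    # shuffle row order so recovery does not depend on generation order
    psms <- psms[sample(nrow(psms)), , drop = FALSE]
    rownames(psms) <- NULL
    truth <- do.call(rbind, truth_rows)
    truth <- truth[order(truth$precursor_id), , drop = FALSE]
    rownames(truth) <- NULL
    list(psms = psms,
         hits = do.call(rbind, hit_rows),
         allowed_motifs = allowed,
         truth = truth)
  })
}

#' Generate planted precursor families for similarity clustering
#'
#' Families are derived from independent random base sequences; members are
#' point-mutated copies at `1 - identity` per-site substitution rate, so
#' intra-family identity is about `identity` and inter-family identity is
#' at the random-background level.
#'
#' @param n_families Number of families.
#' @param members_per_family Sequences per family.
#' @param length Sequence length.
#' @param identity Expected intra-family sequence identity (default 0.8).
#' @param seed Integer seed.
#' @return List with `fasta` (named character vector) and `truth`
#'   (data frame `id`, `family`).
#' @export
gen_precursor_families <- function(n_families = 3L, members_per_family = 20L,
                                   length = 120L, identity = 0.8, seed = 1L) {
  with_seed(sub_seed(seed, "families"), {
    fasta <- character(0)
    truth <- list()
    for (f in seq_len(n_families)) {
      base <- strsplit(.rand_seq(length), "")[[1]]
      for (m in seq_len(members_per_family)) {
        mem <- base
        mut <- stats::runif(length) > identity
        mem[mut] <- sample(.AA, sum(mut), replace = TRUE)
        id <- sprintf("fam%d_mem%02d", f, m)
        fasta[id] <- paste(mem, collapse = "")
        truth[[id]] <- data.frame(id = id, family = f)
      }
    }
    list(fasta = fasta, truth = do.call(rbind, truth))
  })
}

.rand_receptor <- function(id, n_segments = 7L, tm_len = 21L, loop_len = 8L) {
  parts <- character(0)
  segs <- list()
  pos <- 0L
  for (k in seq_len(n_segments)) {
    loop <- .rand_seq(loop_len)
    tm <- .rand_seq(tm_len, .HYDROPHOBIC)
    parts <- c(parts, loop, tm)
    segs[[k]] <- data.frame(start = pos + loop_len,
                            end = pos + loop_len + tm_len)
    pos <- pos + loop_len + tm_len
  }
  parts <- c(parts, .rand_seq(loop_len))
  receptor_model(id, paste(parts, collapse = ""), do.call(rbind, segs))
}

#' Generate a synthetic compound-protein-interaction resource
#'
#' Peptides and 7-TM receptors are generated at random; a planted low-rank
#' bilinear form over the (standardized) z-scale descriptors scores every
#' peptide x receptor pair, and the top `n_positives` pairs are the
#' interactions (labels flipped with probability `label_noise`). Because
#' the decision rule is bilinear in the descriptors it is exactly linear in
#' the linearized outer-product feature space, guaranteeing learnability.
#' Distractor receptors with 5 or 6 TM segments are included to exercise
#' the full-length filter.
#'
#' @param cfg A [gen_config()].
#' @return List with `peptides` (named list of [peptidoform()]),
#'   `receptors` (named list of [receptor_model()], including distractors),
#'   `positives` (data frame `peptide_id`, `receptor_id`, `label`), and
#'   `truth`: the planted score matrix `s` (peptides x receptors), the
#'   noise-free positive set, and `planted_assignment` (the receptor-to-
#'   peptide assignment table computed from the planted scores).
#' @export
gen_cpi <- function(cfg = gen_config()) {
  p <- cfg$cpi
  with_seed(sub_seed(cfg$seed, "cpi"), {
    # The planted rule is a low-rank bilinear form over (scaled, uncentered)
    # z-scale descriptors: s(p, r) = (U' d_p) . (V' d_r). Pure scaling folds
    # into the bilinear form, so the label is exactly linear in the
    # linearized outer-product feature space (guaranteed learnability).
    U <- matrix(stats::rnorm(37 * p$rule_rank), 37)
    V <- matrix(stats::rnorm(35 * p$rule_rank), 35)
    # pilot draws fix the descriptor scaling and a latent-norm acceptance
    # band; keeping projection norms comparable spreads the planted
    # interactions across peptides and receptors instead of letting a few
    # extreme molecules absorb every positive
    pilot_P <- t(vapply(seq_len(300), function(i) {
      peptide_descriptor(.rand_peptide(sample(8:20, 1L)),
                         amidated = stats::runif(1) < 0.8)
    }, numeric(37)))
    pilot_R <- t(vapply(seq_len(150), function(i) {
      receptor_descriptor(.rand_receptor("pilot"))
    }, numeric(35)))
    psd <- pmax(apply(pilot_P, 2, stats::sd), 1e-8)
    rsd <- pmax(apply(pilot_R, 2, stats::sd), 1e-8)
    # orthogonalize the planted factors against the population mean of the
    # (uncentered) descriptors: projections then fluctuate around zero on
    # both sides, so interactions depend on peptide-receptor direction
    # matching rather than on a shared offset, and positives spread over
    # the grid; U and V stay fixed linear maps, preserving bilinearity
    pmu <- colMeans(sweep(pilot_P, 2, psd, "/"))
    rmu <- colMeans(sweep(pilot_R, 2, rsd, "/"))
    U <- U - pmu %o% as.vector(crossprod(pmu, U) / sum(pmu^2))
    V <- V - rmu %o% as.vector(crossprod(rmu, V) / sum(rmu^2))
    pilot_pn <- sqrt(rowSums((sweep(pilot_P, 2, psd, "/") %*% U)^2))
    pilot_rn <- sqrt(rowSums((sweep(pilot_R, 2, rsd, "/") %*% V)^2))
    p_band <- stats::quantile(pilot_pn, c(0.3, 0.7))
    r_band <- stats::quantile(pilot_rn, c(0.3, 0.7))

    draw_until <- function(make, project, band) {
      repeat {
        cand <- make()
        nrm <- sqrt(sum(project(cand)^2))
        if (nrm >= band[1] && nrm <= band[2]) return(cand)
      }
    }
    # peptides and receptors come in families (mutated variants of a
    # template), mirroring real ligand/receptor resources; the family
    # structure concentrates the descriptor population on a low-dimensional
    # manifold, which is what makes the planted rule learnable from a
    # training set of ~1e3 pairs
    n_pf <- max(3L, round(p$n_peptides / 7))
    # receptor families are kept small (~4 members) so that one family fits
    # inside a top-5 ranking window
    n_rf <- max(3L, round(p$n_receptors / 4))
    pep_ids <- sprintf("pep%03d", seq_len(p$n_peptides))
    pep_family <- rep_len(seq_len(n_pf), p$n_peptides)
    pep_templates <- lapply(seq_len(n_pf), function(f) {
      list(seq = draw_until(
             function() .rand_peptide(sample(10:20, 1L)),
             function(s) (peptide_descriptor(s, amidated = FALSE) / psd) %*% U,
             p_band),
           amidated = stats::runif(1) < 0.8)
    })
    seen <- character(0)
    peptides <- stats::setNames(lapply(seq_len(p$n_peptides), function(i) {
      tmpl <- pep_templates[[pep_family[i]]]
      repeat {
        s <- .mutate_seq(tmpl$seq, sample(1:2, 1L))
        if (stats::runif(1) < 0.3) s <- substr(s, 2L, nchar(s))
        if (!(s %in% seen)) break
      }
      seen <<- c(seen, s)
      peptidoform(s, c_amidated = tmpl$amidated)
    }), pep_ids)
    rec_ids <- sprintf("rec%03d", seq_len(p$n_receptors))
    rec_family <- rep_len(seq_len(n_rf), p$n_receptors)
    rec_templates <- lapply(seq_len(n_rf), function(f) {
      draw_until(
        function() .rand_receptor("tmpl"),
        function(r) (receptor_descriptor(r) / rsd) %*% V,
        r_band)
    })
    receptors <- stats::setNames(lapply(seq_len(p$n_receptors), function(i) {
      tmpl <- rec_templates[[rec_family[i]]]
      receptor_model(rec_ids[i], .mutate_seq(tmpl$sequence, 8L),
                     tmpl$tm_segments)
    }), rec_ids)
    if (p$n_distractors > 0L) {
      dst_ids <- sprintf("dst%03d", seq_len(p$n_distractors))
      distractors <- stats::setNames(lapply(seq_along(dst_ids), function(k) {
        .rand_receptor(dst_ids[k], n_segments = sample(5:6, 1L))
      }), dst_ids)
      receptors <- c(receptors, distractors)
    }
    full <- filter_seven_tm(receptors)
    P <- t(vapply(peptides, peptide_descriptor, numeric(37)))
    R <- t(vapply(full, receptor_descriptor, numeric(35)))
    Pz <- sweep(P, 2, psd, "/")
    Rz <- sweep(R, 2, rsd, "/")
    s <- p$rule_strength * (Pz %*% U) %*% t(Rz %*% V)
    dimnames(s) <- list(names(peptides), names(full))
    thr <- sort(as.vector(s), decreasing = TRUE)[p$n_positives]
    ind <- s >= thr
    noise_idx <- which(ind, arr.ind = TRUE)
    noise_free <- data.frame(
      peptide_id = rownames(s)[noise_idx[, 1]],
      receptor_id = colnames(s)[noise_idx[, 2]],
      label = "interact")
    noise_free <- noise_free[order(noise_free$peptide_id,
                                   noise_free$receptor_id), ]
    rownames(noise_free) <- NULL
    if (p$label_noise > 0) {
      # flip every pair's interaction indicator independently: at noise 0.5
      # the recorded interactions carry no information about the rule
      flip <- matrix(stats::runif(length(s)) < p$label_noise,
                     nrow = nrow(s))
      ind <- xor(ind, flip)
    }
    pos_idx <- which(ind, arr.ind = TRUE)
    positives <- data.frame(
      peptide_id = rownames(s)[pos_idx[, 1]],
      receptor_id = colnames(s)[pos_idx[, 2]],
      label = "interact")
    positives <- positives[order(positives$peptide_id, positives$receptor_id), ]
    if (nrow(positives) > p$n_positives) {
      keep <- sort(sample(nrow(positives), p$n_positives))
      positives <- positives[keep, , drop = FALSE]
    }
    rownames(positives) <- NULL
    s_df <- data.frame(
      peptide_id = rep(rownames(s), times = ncol(s)),
      receptor_id = rep(colnames(s), each = nrow(s)),
      score = as.vector(s))
    # planted ligand-receptor pairs: the assignment rule applied to the
    # planted scores, restricted to true (above-threshold) interactions --
    # peptides with no interacting receptor plant nothing
    planted <- assign_receptors(s_df)
    planted <- planted[paste(planted$peptide_id, planted$receptor_id) %in%
                         paste(noise_free$peptide_id, noise_free$receptor_id), ,
                       drop = FALSE]
    # cognate receptor per interacting peptide: its strongest true partner
    cognates <- do.call(rbind, lapply(
      split(noise_free, noise_free$peptide_id), function(df) {
        sv <- s[cbind(df$peptide_id, df$receptor_id)]
        df[order(-sv, df$receptor_id)[1], c("peptide_id", "receptor_id")]
      }))
    rownames(cognates) <- NULL
    # receptor-disjoint target truth: interacting peptides (strongest
    # cognate first) greedily claim up to two of their unclaimed true
    # partners; disjointness lets each receptor mark a single home cluster
    # in the expression stage
    cog_strength <- vapply(seq_len(nrow(cognates)), function(i) {
      s[cognates$peptide_id[i], cognates$receptor_id[i]]
    }, numeric(1))
    claimed <- character(0)
    planted_targets <- do.call(rbind, lapply(
      order(-cog_strength), function(i) {
        pid <- cognates$peptide_id[i]
        mine <- noise_free[noise_free$peptide_id == pid, ]
        mine <- mine[order(-s[cbind(mine$peptide_id, mine$receptor_id)]), ]
        take <- setdiff(mine$receptor_id, claimed)[seq_len(2)]
        take <- take[!is.na(take)]
        claimed <<- c(claimed, take)
        if (!length(take)) return(NULL)
        data.frame(peptide_id = pid, receptor_id = take)
      }))
    planted_targets <- planted_targets[order(planted_targets$peptide_id,
                                             planted_targets$receptor_id), ]
    rownames(planted_targets) <- NULL
    list(peptides = peptides, receptors = receptors, positives = positives,
         truth = list(s = s, noise_free_positives = noise_free,
                      planted_assignment = planted, cognates = cognates,
                      planted_targets = planted_targets))
  })
}

#' Generate a clustered negative-binomial UMI count matrix
#'
#' Cells are split across `n_clusters`; per-gene baseline means are
#' log-normal, with a small fraction of near-silent genes whose totals fall
#' below the standard gene filter. Designated marker genes (typically the
#' planted receptor genes) are elevated `marker_fold`-fold in their home
#' cluster. Counts are negative binomial with the configured dispersion.
#'
#' @param cfg A [gen_config()].
#' @param markers Optional data frame `gene`, `home_cluster` (cluster
#'   labels `"C1"..`); marker genes are appended to (or reused from) the
#'   gene panel.
#' @return List with `umi` (a [umi_matrix()]) and `manifest` (`markers`,
#'   cluster sizes).
#' @export
gen_umi <- function(cfg = gen_config(), markers = NULL) {
  u <- cfg$umi
  with_seed(sub_seed(cfg$seed, "umi"), {
    gene_ids <- sprintf("g%04d", seq_len(u$n_genes))
    if (!is.null(markers)) {
      extra <- setdiff(markers$gene, gene_ids)
      gene_ids <- c(gene_ids, extra)
      if (length(extra)) {
        gene_ids <- gene_ids[seq_len(max(u$n_genes, length(gene_ids)))]
      }
    }
    n_genes <- length(gene_ids)
    clusters <- paste0("C", seq_len(u$n_clusters))
    cluster_of <- stats::setNames(
      sample(clusters, u$n_cells, replace = TRUE),
      sprintf("cell%05d", seq_len(u$n_cells)))
    base <- stats::rlnorm(n_genes, meanlog = -2.3, sdlog = 1)
    # a few near-silent genes to exercise the total-count filter
    silent <- sample(n_genes, max(1L, round(0.02 * n_genes)))
    base[silent] <- 1e-3
    names(base) <- gene_ids
    if (!is.null(markers)) {
      # markers get a solid baseline so the fold change is visible
      base[markers$gene] <- pmax(base[markers$gene], 0.5)
    }
    fold <- matrix(1, nrow = n_genes, ncol = u$n_clusters,
                   dimnames = list(gene_ids, clusters))
    if (!is.null(markers)) {
      for (i in seq_len(nrow(markers))) {
        fold[markers$gene[i], markers$home_cluster[i]] <- u$marker_fold
      }
    }
    counts <- matrix(0L, nrow = n_genes, ncol = u$n_cells,
                     dimnames = list(gene_ids, names(cluster_of)))
    for (k in clusters) {
      cells_k <- which(cluster_of == k)
      mu <- base * fold[, k]
      counts[, cells_k] <- stats::rnbinom(n_genes * length(cells_k),
                                          size = u$dispersion,
                                          mu = rep(mu, times = length(cells_k)))
    }
    sparse <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
    list(umi = umi_matrix(sparse, cluster_of),
         manifest = list(markers = markers,
                         cluster_sizes = table(cluster_of),
                         silent_genes = gene_ids[silent]))
  })
}
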