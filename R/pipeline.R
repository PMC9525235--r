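# End-to-end orchestration over synthetic data: generate -> filter ->
# annotate -> cluster -> predict -> targets, with a single seeded
# configuration, plain-file stage outputs, a JSON run manifest and
# ground-truth recovery metrics.

#' Pipeline configuration
#'
#' Every stage parameter with its standard default: domain-exclusion
#' e-value 1e-10, similarity-cluster e-value cutoff 1e-5, normalization
#' scale factor 10,000, minimum gene total 10, interaction threshold 0.5,
#' at most 5 receptors per peptide.
#'
#' @param seed Master seed for all randomness.
#' @param gen A [gen_config()] (its seed is overridden by `seed`).
#' @param exclusion_evalue Domain-hit exclusion cutoff.
#' @param cluster_cutoff Similarity-graph e-value cutoff.
#' @param scale_factor Per-cell normalization scale (1,000 or 10,000).
#' @param min_gene_total Gene filter threshold.
#' @param threshold Interaction prediction threshold.
#' @param max_per_peptide Receptor assignments kept per peptide.
#' @param kernel SVM kernel for the interaction model.
#' @param stages Character vector of stages to run, a subset of
#'   `c("filter", "annotate", "cluster", "predict", "targets")`.
#' @return A list of class `pipeline_config`. Round-trips through YAML via
#'   [write_pipeline_config()] / [read_pipeline_config()].
#' @export
pipeline_config <- function(seed = 1L,
                            gen = gen_config(seed = seed),
                            exclusion_evalue = 1e-10,
                            cluster_cutoff = 1e-5,
                            scale_factor = 10000,
                            min_gene_total = 10,
                            threshold = 0.5,
                            max_per_peptide = 5L,
                            kernel = "linear",
                            stages = c("filter", "annotate", "cluster",
                                       "predict", "targets")) {
  gen$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), gen = gen,
                 exclusion_evalue = exclusion_evalue,
                 cluster_cutoff = cluster_cutoff,
                 scale_factor = scale_factor,
                 min_gene_total = min_gene_total,
                 threshold = threshold,
                 max_per_peptide = as.integer(max_per_peptide),
                 kernel = kernel,
                 stages = stages),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg A [pipeline_config()].
#' @param path YAML file.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$gen <- unclass(x$gen)
  writeLines(yaml::as.yaml(x), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  gen <- do.call(gen_config, x$gen[setdiff(names(x$gen), character(0))])
  do.call(pipeline_config, c(list(gen = gen),
                             x[setdiff(names(x), "gen")]))
}

#' Round-trip recovery of planted precursor structure
#'
#' Builds annotations from the generator manifest, maps the planted
#' peptides back onto the emitted precursors, classifies sites and donors,
#' and scores agreement with the manifest.
#'
#' @param fasta Named character vector of precursor sequences.
#' @param manifest Manifest from [gen_precursors()].
#' @return List with `span_recovery`, `site_class_recovery`,
#'   `donor_recovery` (fractions in \[0,1\]) and `annotations` (the list of
#'   classified [precursor_annotation()] objects).
#' @export
annotation_recovery <- function(fasta, manifest) {
  pep <- manifest$peptides
  anns <- list()
  n_spans_found <- 0L
  n_sites_ok <- 0L
  n_sites <- 0L
  n_donor_ok <- 0L
  for (id in unique(pep$precursor_id)) {
    rows <- pep[pep$precursor_id == id, , drop = FALSE]
    ann <- precursor_annotation(id, fasta[[id]],
                                peptides = unique(rows$peptide),
                                amidated = rows$amidated[1])
    ann <- classify_sites(ann)
    anns[[id]] <- ann
    spans <- ann$peptide_spans
    keys_found <- paste(spans$start, spans$end)
    keys_true <- paste(rows$start, rows$end)
    n_spans_found <- n_spans_found + sum(keys_true %in% keys_found)
    cs <- ann$cleavage_sites
    for (i in seq_len(nrow(rows))) {
      n_sites <- n_sites + 2L
      ncls <- cs$cls[cs$side == "n_terminal" & cs$position == rows$start[i]]
      ccls <- cs$cls[cs$side == "c_terminal" &
                       cs$position == rows$end[i] + as.integer(rows$donor[i])]
      if (length(ncls) && ncls[1] == rows$n_class[i]) n_sites_ok <- n_sites_ok + 1L
      if (length(ccls) && ccls[1] == rows$c_class[i]) n_sites_ok <- n_sites_ok + 1L
    }
    donors <- detect_amide_donor(ann)$donor
    for (i in seq_len(nrow(rows))) {
      j <- which(spans$start == rows$start[i] & spans$end == rows$end[i])
      if (length(j) && donors[j[1]] == rows$donor[i]) n_donor_ok <- n_donor_ok + 1L
    }
  }
  list(span_recovery = n_spans_found / nrow(pep),
       site_class_recovery = n_sites_ok / n_sites,
       donor_recovery = n_donor_ok / nrow(pep),
       annotations = anns)
}

#' K/R frequency in the site columns of cleavage-context matrices
#'
#' @param ctx Result of [cleavage_context()].
#' @param site_len Site width used when building the context (default 2).
#' @return Fraction of site-column observations that are K or R.
#' @export
context_basic_fraction <- function(ctx, site_len = 2L) {
  ncols <- ncol(ctx$n_terminal$counts)
  n_site <- ctx$n_terminal$counts[, seq(ncols - site_len + 1L, ncols), drop = FALSE]
  c_site <- ctx$c_terminal$counts[, seq_len(site_len), drop = FALSE]
  tot <- sum(n_site) + sum(c_site)
  kr <- sum(n_site[c("K", "R"), ]) + sum(c_site[c("K", "R"), ])
  kr / tot
}

#' Compare a recovered partition with a planted one
#'
#' @param parts Data frame `id`, `cluster` from [components()].
#' @param truth Data frame `id`, `family`.
#' @return `TRUE` iff the two partitions are identical (label-agnostic).
#' @export
partition_matches <- function(parts, truth) {
  m <- merge(parts, truth, by = "id")
  tab <- table(m$cluster, m$family)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

#' Build outer-product features for labelled CPI pairs
#'
#' @param peptides Named list of [peptidoform()]s.
#' @param receptors Named list of full-length [receptor_model()]s.
#' @param pairs Data frame with `peptide_id`, `receptor_id`.
#' @return Feature matrix, one row per pair.
#' @export
build_cpi_features <- function(peptides, receptors, pairs) {
  pvecs <- lapply(peptides, peptide_descriptor)
  rvecs <- lapply(receptors, receptor_descriptor)
  t(mapply(function(p, r) linearized_outer_product(pvecs[[p]], rvecs[[r]]),
           pairs$peptide_id, pairs$receptor_id))
}

# Rank-based (Mann-Whitney) area under the ROC curve
.auc <- function(labels01, scores) {
  r <- rank(scores)
  n1 <- sum(labels01 == 1)
  n0 <- sum(labels01 == 0)
  (sum(r[labels01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Held-out evaluation of the CPI interaction model
#'
#' Generates shuffle negatives for the positive set, splits pairs into
#' train/test (stratified, seeded), trains the SVM on the training split
#' and reports the test-set ROC AUC, then refits on all pairs for
#' downstream prediction.
#'
#' @param cpi Result of [gen_cpi()] (or a list with `peptides`,
#'   `receptors`, `positives`).
#' @param seed Integer seed (negatives, split, permutation).
#' @param holdout Test fraction (default 0.3).
#' @param kernel SVM kernel.
#' @param permute_labels If `TRUE`, training labels are permuted (null
#'   control); the held-out AUC should then collapse to chance.
#' @return List with `auc`, `model` (fit on all pairs; `NULL` when
#'   `permute_labels`), `pairs` (the labelled pair table used).
#' @export
cpi_holdout_eval <- function(cpi, seed = 1L, holdout = 0.3,
                             kernel = "linear", permute_labels = FALSE) {
  full <- filter_seven_tm(cpi$receptors)
  positives <- cpi$positives[cpi$positives$label == "interact", , drop = FALSE]
  negatives <- generate_negatives(positives, ratio = 1,
                                  seed = sub_seed(seed, "negatives"))
  pairs <- rbind(positives[c("peptide_id", "receptor_id", "label")],
                 negatives[c("peptide_id", "receptor_id", "label")])
  feats <- build_cpi_features(cpi$peptides, full, pairs)
  labels <- pairs$label
  if (permute_labels) {
    labels <- with_seed(sub_seed(seed, "permute"), sample(labels))
  }
  is_pos <- labels == "interact"
  test_idx <- with_seed(sub_seed(seed, "split"), {
    c(sample(which(is_pos), round(holdout * sum(is_pos))),
      sample(which(!is_pos), round(holdout * sum(!is_pos))))
  })
  train <- setdiff(seq_len(nrow(pairs)), test_idx)
  model <- train_cpi_model(feats[train, , drop = FALSE], labels[train],
                           kernel = kernel, seed = seed)
  scores <- score_pairs(model, feats[test_idx, , drop = FALSE])
  auc <- .auc(as.numeric(labels[test_idx] == "interact"), scores)
  full_model <- if (permute_labels) NULL else
    train_cpi_model(feats, labels, kernel = kernel, seed = seed)
  list(auc = auc, model = full_model, pairs = pairs)
}

#' Run the full pipeline on synthetic data
#'
#' Executes generate -> filter -> annotate -> cluster -> predict ->
#' targets, writing every stage output as a plain file under `out_dir`
#' together with a JSON run manifest (seed, parameters, output digests)
#' and a `metrics.json` of ground-truth recovery measures. Deterministic:
#' the same configuration yields byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `metrics`, `paths` and the stage results.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  syn_dir <- file.path(out_dir, "synthetic")
  dir.create(syn_dir, showWarnings = FALSE)
  metrics <- list()
  results <- list()

  # --- generate -------------------------------------------------------
  prec <- gen_precursors(cfg$gen)
  verify_precursor_truth(prec$fasta, prec$manifest)
  write_fasta(prec$fasta, file.path(syn_dir, "precursors.fasta"))
  write_tsv(prec$manifest$peptides, file.path(syn_dir, "planted_peptides.tsv"))
  psm <- gen_psm_table(cfg$gen, prec$manifest)
  write_psm_table(psm$psms, file.path(syn_dir, "psms.tsv"))
  write_tsv(psm$hits, file.path(syn_dir, "domain_hits.tsv"))
  fams <- gen_precursor_families(seed = cfg$seed)
  write_fasta(fams$fasta, file.path(syn_dir, "families.fasta"))
  cpi <- gen_cpi(cfg$gen)
  write_tsv(cpi$positives, file.path(syn_dir, "cpi_positives.tsv"))
  write_peptides(cpi$peptides, file.path(syn_dir, "cpi_peptides.tsv"))
  write_receptors(cpi$receptors, file.path(syn_dir, "receptors.fasta"),
                  file.path(syn_dir, "receptor_tms.tsv"))

  # --- filter ---------------------------------------------------------
  if ("filter" %in% cfg$stages) {
    records <- read_psm_table(file.path(syn_dir, "psms.tsv"))
    hits <- read_domain_hits(file.path(syn_dir, "domain_hits.tsv"))
    fcfg <- filter_config(allowed_motifs = psm$allowed_motifs,
                          exclusion_evalue = cfg$exclusion_evalue)
    curated <- run_filter(records, hits, fcfg)
    curated <- curated[order(curated$precursor_id), , drop = FALSE]
    write_psm_table(curated, file.path(out_dir, "curated_peptides.tsv"))
    got <- curated[c("precursor_id", "sequence", "score")]
    rownames(got) <- NULL
    metrics$psm_exact_recovery <- as.numeric(isTRUE(all.equal(got, psm$truth,
                                                              check.attributes = FALSE)))
    results$curated <- curated
  }

  # --- annotate -------------------------------------------------------
  if ("annotate" %in% cfg$stages) {
    rec <- annotation_recovery(prec$fasta, prec$manifest)
    metrics$span_recovery <- rec$span_recovery
    metrics$site_class_recovery <- rec$site_class_recovery
    metrics$donor_recovery <- rec$donor_recovery
    ctx <- cleavage_context(rec$annotations)
    metrics$site_basic_fraction <- context_basic_fraction(ctx)
    write_context_matrix(ctx$n_terminal, file.path(out_dir, "context_nterm.tsv"))
    write_context_matrix(ctx$c_terminal, file.path(out_dir, "context_cterm.tsv"))
    all_sites <- do.call(rbind, lapply(rec$annotations, function(a) {
      cbind(precursor_id = a$precursor_id, a$cleavage_sites)
    }))
    rownames(all_sites) <- NULL
    write_tsv(all_sites, file.path(out_dir, "cleavage_sites.tsv"))
    results$annotations <- rec$annotations
  }

  # --- cluster --------------------------------------------------------
  if ("cluster" %in% cfg$stages) {
    graph <- build_graph(fams$fasta, cutoff = cfg$cluster_cutoff)
    parts <- components(graph)
    write_tsv(graph$edges, file.path(out_dir, "cluster_edges.tsv"))
    write_tsv(parts, file.path(out_dir, "clusters.tsv"))
    metrics$family_partition_exact <-
      as.numeric(partition_matches(parts, fams$truth))
    results$partition <- parts
  }

  # --- predict --------------------------------------------------------
  if ("predict" %in% cfg$stages) {
    eval <- cpi_holdout_eval(cpi, seed = cfg$seed, kernel = cfg$kernel)
    metrics$cpi_holdout_auc <- eval$auc
    full <- filter_seven_tm(cpi$receptors)
    pred <- predict_pairs(eval$model, cpi$peptides, full,
                          threshold = cfg$threshold)
    assignments <- assign_receptors(pred$scores,
                                    max_per_peptide = cfg$max_per_peptide)
    write_tsv(pred$scores, file.path(out_dir, "cpi_scores.tsv"))
    write_tsv(pred$predicted, file.path(out_dir, "predicted_pairs.tsv"))
    write_tsv(assignments, file.path(out_dir, "assignments.tsv"))
    truth_pairs <- paste(cpi$truth$planted_assignment$peptide_id,
                         cpi$truth$planted_assignment$receptor_id)
    got_pairs <- paste(assignments$peptide_id, assignments$receptor_id)
    metrics$assignment_recovery <- mean(truth_pairs %in% got_pairs)
    top5 <- top_receptors(pred$scores, k = cfg$max_per_peptide)
    cog <- cpi$truth$cognates
    metrics$cognate_top5_recovery <-
      mean(paste(cog$peptide_id, cog$receptor_id) %in%
             paste(top5$peptide_id, top5$receptor_id))
    # per interacting ligand: do its top-5 predicted receptors include a
    # planted partner?
    nf <- cpi$truth$noise_free_positives
    key_nf <- paste(nf$peptide_id, nf$receptor_id)
    metrics$ligand_target_recovery <- mean(vapply(
      unique(nf$peptide_id), function(p) {
        t5 <- top5[top5$peptide_id == p, ]
        any(paste(t5$peptide_id, t5$receptor_id) %in% key_nf)
      }, logical(1)))
    results$assignments <- assignments
  }

  # --- targets --------------------------------------------------------
  if ("targets" %in% cfg$stages) {
    truth_assign <- cpi$truth$planted_targets
    pep_ids <- sort(unique(truth_assign$peptide_id))
    home <- stats::setNames(
      paste0("C", (seq_along(pep_ids) - 1L) %% cfg$gen$umi$n_clusters + 1L),
      pep_ids)
    markers <- data.frame(gene = truth_assign$receptor_id,
                          home_cluster = unname(home[truth_assign$peptide_id]))
    gen <- gen_umi(cfg$gen, markers = markers)
    write_umi_matrix(gen$umi, file.path(syn_dir, "umi"))
    nm <- normalize_cells(gen$umi, scale_factor = cfg$scale_factor)
    metrics$normalized_total_max_abs_error <-
      max(abs(Matrix::colSums(nm$values) - cfg$scale_factor))
    filtered <- filter_genes(gen$umi, min_total = cfg$min_gene_total)
    nm$values <- nm$values[rownames(filtered$counts), , drop = FALSE]
    ce <- scale_by_gene(cluster_means(nm))
    tg <- peptide_cell_targets(truth_assign, ce)
    write_tsv(cbind(gene = rownames(ce$normalized_mean),
                    as.data.frame(as.matrix(ce$normalized_mean))),
              file.path(out_dir, "cluster_means.tsv"))
    write_tsv(cbind(peptide_id = rownames(tg$targets),
                    as.data.frame(tg$targets)),
              file.path(out_dir, "peptide_targets.tsv"))
    hottest <- colnames(tg$targets)[apply(tg$targets, 1, which.max)]
    metrics$target_cluster_recovery <-
      mean(hottest == home[rownames(tg$targets)])
    results$targets <- tg
  }

  # --- manifest -------------------------------------------------------
  outputs <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                          c("manifest.json", "metrics.json")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("neuropep")),
    seed = cfg$seed,
    parameters = unclass(cfg[setdiff(names(cfg), "gen")]),
    gen = unclass(cfg$gen),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(metrics = metrics, out_dir = out_dir, results = results,
                 truth = list(precursors = prec$manifest, psm = psm$truth,
                              families = fams$truth, cpi = cpi$truth)))
}
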