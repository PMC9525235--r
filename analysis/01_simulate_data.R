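#!/usr/bin/env Rscript

# Step 1 -- simulate every upstream input of the peptidomics pipeline:
# precursor FASTA with planted peptide architecture, a peptide-spectrum-
# match table with contaminants, precursor families for similarity
# clustering, a compound-protein-interaction training resource with 7-TM
# receptors, and a clustered UMI count matrix. Ground-truth manifests are
# written next to each input so later steps can score their recovery.

suppressPackageStartupMessages(library(neuropep))

seed <- 1L
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- gen_config(seed = seed)

prec <- gen_precursors(cfg)
verify_precursor_truth(prec$fasta, prec$manifest)
write_fasta(prec$fasta, file.path(out, "precursors.fasta"))
write_tsv(prec$manifest$peptides, file.path(out, "planted_peptides.tsv"))
write_tsv(prec$manifest$signal_peptides, file.path(out, "signal_peptides.tsv"))
message(sprintf("precursors: %d sequences, %d planted peptide copies",
                length(prec$fasta), nrow(prec$manifest$peptides)))

psm <- gen_psm_table(cfg, prec$manifest)
write_psm_table(psm$psms, file.path(out, "psms.tsv"))
write_tsv(psm$hits, file.path(out, "domain_hits.tsv"))
writeLines(psm$allowed_motifs, file.path(out, "allowed_motifs.txt"))
write_tsv(psm$truth, file.path(out, "psm_truth.tsv"))
message(sprintf("PSM table: %d records (%d curated-truth rows)",
                nrow(psm$psms), nrow(psm$truth)))

fams <- gen_precursor_families(3, 20, 120, 0.8, seed = seed)
write_fasta(fams$fasta, file.path(out, "families.fasta"))
write_tsv(fams$truth, file.path(out, "family_truth.tsv"))

cpi <- gen_cpi(cfg)
write_tsv(cpi$positives, file.path(out, "cpi_positives.tsv"))
write_peptides(cpi$peptides, file.path(out, "cpi_peptides.tsv"))
write_receptors(cpi$receptors, file.path(out, "receptors.fasta"),
                file.path(out, "receptor_tms.tsv"))
write_tsv(cpi$truth$noise_free_positives, file.path(out, "cpi_truth_pairs.tsv"))
write_tsv(cpi$truth$planted_targets, file.path(out, "cpi_truth_assignment.tsv"))
message(sprintf("CPI resource: %d peptides, %d receptors (%d full-length), %d positives",
                length(cpi$peptides), length(cpi$receptors),
                length(filter_seven_tm(cpi$receptors)), nrow(cpi$positives)))

# receptor markers for the single-cell stage: each interacting peptide's
# planted receptors mark a home cluster
truth_assign <- cpi$truth$planted_targets
pep_ids <- sort(unique(truth_assign$peptide_id))
home <- stats::setNames(paste0("C", (seq_along(pep_ids) - 1L) %% cfg$umi$n_clusters + 1L),
                        pep_ids)
markers <- data.frame(gene = truth_assign$receptor_id,
                      home_cluster = unname(home[truth_assign$peptide_id]))
write_tsv(markers, file.path(out, "marker_truth.tsv"))
umi <- gen_umi(cfg, markers = markers)
write_umi_matrix(umi$umi, file.path(out, "umi"))
message(sprintf("UMI matrix: %d genes x %d cells over %d clusters",
                nrow(umi$umi$counts), ncol(umi$umi$counts), cfg$umi$n_clusters))
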