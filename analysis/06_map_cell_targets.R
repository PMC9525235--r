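#!/usr/bin/env Rscript

# Step 6 -- single-cell target mapping: normalize UMI counts per cell
# (molecules per 10,000 UMIs), drop genes with totals under 10, average
# per cluster, scale per gene for dot plots, and sum the normalized
# expression of each peptide's assigned receptors per cluster to locate
# its target cell types.

suppressPackageStartupMessages(library(neuropep))

syn <- "results/synthetic"
umi <- read_umi_matrix(file.path(syn, "umi/counts.mtx"),
                       file.path(syn, "umi/genes.tsv"),
                       file.path(syn, "umi/cells.tsv"),
                       file.path(syn, "umi/clusters.tsv"))

nm <- normalize_cells(umi, scale_factor = 10000)
message(sprintf("normalized %d cells; per-cell total error <= %.2g",
                ncol(nm$values), max(abs(Matrix::colSums(nm$values) - 10000))))

filtered <- filter_genes(umi, min_total = 10)
nm$values <- nm$values[rownames(filtered$counts), , drop = FALSE]
message(sprintf("%d of %d genes pass the total-count filter",
                nrow(filtered$counts), nrow(umi$counts)))

ce <- scale_by_gene(cluster_means(nm))
write_tsv(cbind(gene = rownames(ce$normalized_mean),
                as.data.frame(as.matrix(ce$normalized_mean))),
          "results/cluster_means.tsv")
write_tsv(cbind(gene = rownames(ce$scaled), as.data.frame(as.matrix(ce$scaled))),
          "results/cluster_means_scaled.tsv")

assignments <- read_tsv(file.path(syn, "cpi_truth_assignment.tsv"))
tg <- peptide_cell_targets(assignments, ce)
write_tsv(cbind(peptide_id = rownames(tg$targets), as.data.frame(tg$targets)),
          "results/peptide_targets.tsv")

markers <- read_tsv(file.path(syn, "marker_truth.tsv"))
home <- tapply(markers$home_cluster, assignments$peptide_id[
  match(markers$gene, assignments$receptor_id)], function(x) x[1])
hottest <- colnames(tg$targets)[apply(tg$targets, 1, which.max)]
message(sprintf("hottest target cluster matches the planted home cluster for %.1f%% of peptides",
                100 * mean(hottest == home[rownames(tg$targets)])))
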