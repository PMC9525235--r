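#!/usr/bin/env Rscript

# Step 3 -- precursor annotation: map planted peptides back onto their
# precursors, classify the flanking cleavage sites (dibasic vs acidic),
# detect glycine amide donors, and emit logo-ready cleavage-context
# matrices for the two-residue site plus six-residue flank windows.

suppressPackageStartupMessages(library(neuropep))

syn <- "results/synthetic"
fasta <- read_fasta(file.path(syn, "precursors.fasta"))
manifest <- list(peptides = read_tsv(file.path(syn, "planted_peptides.tsv")))

rec <- annotation_recovery(fasta, manifest)
message(sprintf("span recovery %.1f%%, site-class recovery %.1f%%, donor recovery %.1f%%",
                100 * rec$span_recovery, 100 * rec$site_class_recovery,
                100 * rec$donor_recovery))

sites <- do.call(rbind, lapply(rec$annotations, function(a) {
  cbind(precursor_id = a$precursor_id, a$cleavage_sites)
}))
rownames(sites) <- NULL
write_tsv(sites, "results/cleavage_sites.tsv")

ctx <- cleavage_context(rec$annotations, site_len = 2, flank_len = 6)
write_context_matrix(ctx$n_terminal, "results/context_nterm.tsv")
write_context_matrix(ctx$c_terminal, "results/context_cterm.tsv")
message(sprintf("site columns: %.1f%% K/R (planted 70%%) over %d junction windows",
                100 * context_basic_fraction(ctx),
                ctx$n_terminal$n_windows + ctx$c_terminal$n_windows))
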