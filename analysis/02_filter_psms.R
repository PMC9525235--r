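#!/usr/bin/env Rscript

# Step 2 -- post-search filtering of peptide-spectrum matches: remove
# peptides whose precursor carries a non-neuropeptide domain hit at
# e <= 1e-10, keep C-terminally amidated identifications, and keep one
# top-scoring representative per precursor. Scores the curated list
# against the planted truth.

suppressPackageStartupMessages(library(neuropep))

syn <- "results/synthetic"
records <- read_psm_table(file.path(syn, "psms.tsv"))
hits <- read_domain_hits(file.path(syn, "domain_hits.tsv"))
allowed <- readLines(file.path(syn, "allowed_motifs.txt"))

cfg <- filter_config(allowed_motifs = allowed, exclusion_evalue = 1e-10)
curated <- run_filter(records, hits, cfg)
curated <- curated[order(curated$precursor_id), ]
write_psm_table(curated, "results/curated_peptides.tsv")

truth <- read_tsv(file.path(syn, "psm_truth.tsv"))
got <- curated[c("precursor_id", "sequence", "score")]
rownames(got) <- NULL
exact <- isTRUE(all.equal(got, truth, check.attributes = FALSE,
                          tolerance = 1e-8))
message(sprintf("curated %d of %d records; exact match to planted truth: %s",
                nrow(curated), nrow(records), exact))
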