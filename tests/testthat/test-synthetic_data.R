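test_that("generator configuration validates fractions", {
  expect_error(gen_config(basic_site_fraction = 1.2))
  expect_error(gen_config(cpi = list(label_noise = 2)))
  cfg <- gen_config(seed = 5, cpi = list(n_peptides = 10))
  expect_equal(cfg$cpi$n_peptides, 10)
  expect_equal(cfg$cpi$n_positives, 600L)  # untouched defaults survive
})

test_that("precursor generation honors the site-composition dials", {
  cfg_b <- gen_config(seed = 71, n_precursors = 15, basic_site_fraction = 1)
  g <- gen_precursors(cfg_b)
  expect_true(all(g$manifest$peptides$n_class == "basic"))
  expect_true(all(g$manifest$peptides$c_class == "basic"))
  expect_false(any(grepl("[DE]", c(g$manifest$peptides$n_site,
                                   g$manifest$peptides$c_site))))
  cfg_a <- gen_config(seed = 71, n_precursors = 15, amidated_fraction = 1)
  g2 <- gen_precursors(cfg_a)
  expect_true(all(g2$manifest$peptides$donor))
  # every amidated copy is followed by G in the emitted sequence
  pep <- g2$manifest$peptides
  for (i in seq_len(nrow(pep))) {
    expect_equal(substr(g2$fasta[[pep$precursor_id[i]]],
                        pep$end[i] + 1, pep$end[i] + 1), "G")
  }
})

test_that("manifests are re-verifiable from the emitted sequences", {
  g <- gen_precursors(gen_config(seed = 72, n_precursors = 25))
  expect_true(verify_precursor_truth(g$fasta, g$manifest))
  # corrupting a span must be caught
  bad <- g$manifest
  bad$peptides$start[1] <- bad$peptides$start[1] + 1L
  expect_error(verify_precursor_truth(g$fasta, bad), "mismatch")
})

test_that("generators are byte-reproducible and respond to the master seed", {
  cfg <- gen_config(seed = 73, n_precursors = 10)
  expect_identical(gen_precursors(cfg), gen_precursors(cfg))
  expect_identical(gen_psm_table(cfg, gen_precursors(cfg)$manifest),
                   gen_psm_table(cfg, gen_precursors(cfg)$manifest))
  cfg2 <- gen_config(seed = 74, n_precursors = 10)
  expect_false(identical(gen_precursors(cfg)$fasta, gen_precursors(cfg2)$fasta))
  # generators do not disturb the caller's RNG stream
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(gen_precursors(cfg))
  expect_identical(runif(1), before)
})

test_that("a decoy-free PSM table passes the filter unchanged on the amidated set", {
  cfg <- gen_config(seed = 75, n_precursors = 20, psm_decoy_fraction = 0)
  g <- gen_precursors(cfg)
  ps <- gen_psm_table(cfg, g$manifest)
  expect_false(any(grepl("^contam", ps$psms$precursor_id)))
  out <- run_filter(ps$psms, ps$hits, filter_config(allowed_motifs = ps$allowed_motifs))
  out <- out[order(out$precursor_id), ]
  got <- out[c("precursor_id", "sequence", "score")]
  rownames(got) <- NULL
  expect_equal(got, ps$truth, ignore_attr = TRUE)
})

test_that("CPI distractor receptors all fall to the seven-TM filter", {
  cfg <- gen_config(seed = 76, cpi = list(n_peptides = 12, n_receptors = 12,
                                          n_distractors = 5, n_positives = 30))
  cpi <- gen_cpi(cfg)
  expect_length(cpi$receptors, 17)
  full <- filter_seven_tm(cpi$receptors)
  expect_length(full, 12)
  expect_false(any(grepl("^dst", names(full))))
  # positives reference only full-length receptors
  expect_true(all(cpi$positives$receptor_id %in% names(full)))
  # peptide length precondition for descriptors holds
  expect_true(all(vapply(cpi$peptides, function(p) nchar(p$sequence) >= 3,
                         logical(1))))
})

test_that("planted cognates are the argmax of the planted scores among partners", {
  cfg <- gen_config(seed = 77, cpi = list(n_peptides = 20, n_receptors = 20,
                                          n_positives = 60))
  cpi <- gen_cpi(cfg)
  s <- cpi$truth$s
  nf <- cpi$truth$noise_free_positives
  cog <- cpi$truth$cognates
  for (i in seq_len(nrow(cog))) {
    partners <- nf$receptor_id[nf$peptide_id == cog$peptide_id[i]]
    best <- partners[which.max(s[cog$peptide_id[i], partners])]
    expect_equal(cog$receptor_id[i], best)
  }
})

test_that("UMI generation plants markers, silent genes and cluster labels", {
  cfg <- gen_config(seed = 78, umi = list(n_genes = 300, n_cells = 400,
                                          n_clusters = 5, marker_fold = 8))
  mk <- data.frame(gene = c("recX", "recY"), home_cluster = c("C2", "C4"))
  g <- gen_umi(cfg, markers = mk)
  expect_true(all(mk$gene %in% rownames(g$umi$counts)))
  expect_equal(ncol(g$umi$counts), 400L)
  expect_setequal(unique(unname(g$umi$cluster_of)), paste0("C", 1:5))
  # silent genes exercise the total-count filter
  expect_true(any(Matrix::rowSums(g$umi$counts) < 10))
  # marker cluster-mean argmax is the home cluster at fold 8
  nm <- normalize_cells(g$umi, 10000)
  ce <- cluster_means(nm)
  expect_equal(colnames(ce$normalized_mean)[which.max(ce$normalized_mean["recX", ])],
               "C2")
  expect_equal(colnames(ce$normalized_mean)[which.max(ce$normalized_mean["recY", ])],
               "C4")
  # reproducible
  expect_identical(as.matrix(gen_umi(cfg, mk)$umi$counts),
                   as.matrix(g$umi$counts))
})

test_that("marker_fold = 1 leaves no planted cluster structure", {
  cfg <- gen_config(seed = 79, umi = list(n_genes = 200, n_cells = 600,
                                          n_clusters = 4, marker_fold = 1))
  mk <- data.frame(gene = "recZ", home_cluster = "C3")
  g <- gen_umi(cfg, markers = mk)
  nm <- normalize_cells(g$umi, 10000)
  ce <- cluster_means(nm)
  vals <- ce$normalized_mean["recZ", ]
  # the home cluster should not stand out: spread within noise range
  expect_lt(max(vals) / max(min(vals), 1e-9), 2)
})

test_that("UMI matrices round-trip through MTX + TSV files", {
  cfg <- gen_config(seed = 80, umi = list(n_genes = 50, n_cells = 40,
                                          n_clusters = 3))
  g <- gen_umi(cfg)
  dir <- withr::local_tempdir()
  write_umi_matrix(g$umi, dir)
  back <- read_umi_matrix(file.path(dir, "counts.mtx"),
                          file.path(dir, "genes.tsv"),
                          file.path(dir, "cells.tsv"),
                          file.path(dir, "clusters.tsv"))
  expect_equal(as.matrix(back$counts), as.matrix(g$umi$counts))
  expect_equal(back$cluster_of, g$umi$cluster_of)
})

test_that("precursor FASTA files round-trip", {
  g <- gen_precursors(gen_config(seed = 81, n_precursors = 5))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(g$fasta, f)
  expect_equal(read_fasta(f), g$fasta)
})
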