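toy_umi <- function(counts, clusters) {
  umi_matrix(counts, stats::setNames(clusters, colnames(counts)))
}

test_that("the gene filter drops totals strictly below the threshold", {
  counts <- matrix(c(3, 3, 3,   4, 3, 3,   5, 3, 3), nrow = 3, byrow = TRUE,
                   dimnames = list(c("g9", "g10", "g11"), c("c1", "c2", "c3")))
  m <- toy_umi(counts, rep("C1", 3))
  f <- filter_genes(m, min_total = 10)
  expect_equal(rownames(f$counts), c("g10", "g11"))  # totals 9, 10, 11
  expect_equal(ncol(f$counts), 3L)
  expect_equal(rownames(filter_genes(m, 0)$counts), rownames(counts))
  expect_warning(filter_genes(m, 1e6), "all genes removed")
})

test_that("the gene filter agrees with a brute-force row-sum filter", {
  set.seed(61)
  counts <- matrix(rpois(200, 2), 20,
                   dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  m <- toy_umi(counts, rep(c("C1", "C2"), 5))
  f <- filter_genes(m, 15)
  expect_equal(rownames(f$counts), rownames(counts)[rowSums(counts) >= 15])
})

test_that("per-cell normalization yields molecules per scale_factor UMIs", {
  counts <- matrix(c(7, 0, 2, 3), 2,
                   dimnames = list(c("g1", "g2"), c("c1", "c2")))
  m <- toy_umi(counts, c("C1", "C1"))
  nm <- normalize_cells(m, 10000)
  expect_equal(unname(as.matrix(nm$values)[, "c1"]), c(10000, 0))
  expect_equal(unname(colSums(as.matrix(nm$values))), c(10000, 10000))
  # brute-force division oracle on a random matrix
  set.seed(62)
  counts2 <- matrix(rpois(60, 3) + 1, 6,
                    dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  m2 <- toy_umi(counts2, rep("C1", 10))
  nm2 <- normalize_cells(m2, 1000)
  oracle <- sweep(counts2, 2, colSums(counts2), "/") * 1000
  expect_equal(as.matrix(nm2$values), oracle)
})

test_that("cells with zero totals are dropped with a warning", {
  counts <- matrix(c(5, 5, 0, 0), 2,
                   dimnames = list(c("g1", "g2"), c("c1", "c2")))
  m <- toy_umi(counts, c("C1", "C2"))
  expect_warning(nm <- normalize_cells(m, 100), "zero total")
  expect_equal(colnames(nm$values), "c1")
})

test_that("cluster means are per-cluster arithmetic means, order-invariant", {
  counts <- matrix(c(2, 0,  4, 0,  0, 6), 2,
                   dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  m <- toy_umi(counts, c("C1", "C1", "C2"))
  nm <- normalize_cells(m, 10)
  ce <- cluster_means(nm)
  # one-cell cluster C2 equals the cell's values
  expect_equal(unname(ce$normalized_mean[, "C2"]),
               unname(as.matrix(nm$values)[, "c3"]))
  expect_equal(unname(ce$normalized_mean["g1", "C1"]),
               mean(as.matrix(nm$values)["g1", c("c1", "c2")]))
  # permuting cells leaves cluster means unchanged
  perm <- c("c3", "c1", "c2")
  m2 <- toy_umi(counts[, perm], c("C2", "C1", "C1"))
  ce2 <- cluster_means(normalize_cells(m2, 10))
  expect_equal(ce2$normalized_mean, ce$normalized_mean)
})

test_that("cluster means agree with a group-by oracle on a random matrix", {
  set.seed(63)
  counts <- matrix(rpois(300, 4), 10,
                   dimnames = list(paste0("g", 1:10), paste0("c", 1:30)))
  cl <- sample(c("C1", "C2", "C3"), 30, replace = TRUE)
  nm <- normalize_cells(toy_umi(counts, cl), 1000)
  ce <- cluster_means(nm)
  vals <- as.matrix(nm$values)
  for (k in unique(cl)) {
    expect_equal(unname(ce$normalized_mean[, k]),
                 unname(rowMeans(vals[, cl == k, drop = FALSE])))
  }
})

test_that("per-gene scaling maps rows into [0,1] with max 1, zeros preserved", {
  ce <- structure(list(genes = c("g1", "g2"), clusters = c("C1", "C2"),
                       normalized_mean = matrix(c(2, 0, 4, 0), 2,
                                                dimnames = list(c("g1", "g2"),
                                                                c("C1", "C2"))),
                       scaled = NULL), class = "cluster_expression")
  out <- scale_by_gene(ce)
  expect_equal(unname(out$scaled["g1", ]), c(0.5, 1.0))
  expect_equal(unname(out$scaled["g2", ]), c(0, 0))
  set.seed(64)
  ce$normalized_mean <- matrix(runif(20), 2, 10,
                               dimnames = list(c("g1", "g2"), paste0("C", 1:10)))
  out2 <- scale_by_gene(ce)
  expect_true(all(out2$scaled >= 0 & out2$scaled <= 1))
  expect_equal(unname(apply(out2$scaled, 1, max)), c(1, 1))
})

test_that("the highest-expressed homologue is selected per family", {
  ce <- structure(list(genes = c("gA", "gB", "gC"), clusters = c("C1", "C2"),
                       normalized_mean = matrix(c(2, 3, 1, 3, 6, 0), 3,
                                                dimnames = list(c("gA", "gB", "gC"),
                                                                c("C1", "C2"))),
                       scaled = NULL), class = "cluster_expression")
  fams <- list(f1 = c("gA", "gB"), f2 = "gC", f3 = c("gX", "gY"))
  out <- top_homologue_per_family(ce, fams)
  expect_equal(out$top[["f1"]], "gB")  # sums 5 vs 9
  expect_equal(out$top[["f2"]], "gC")
  expect_equal(out$missing, "f3")
})

test_that("peptide cell targets are receptor-row sums, additive in the receptor set", {
  nmv <- matrix(c(1, 2, 3, 10, 20, 30, 100, 200, 300), 3, byrow = TRUE,
                dimnames = list(c("r1", "r2", "r3"), c("C1", "C2", "C3")))
  ce <- structure(list(genes = rownames(nmv), clusters = colnames(nmv),
                       normalized_mean = nmv, scaled = NULL),
                  class = "cluster_expression")
  one <- peptide_cell_targets(data.frame(peptide_id = "p", receptor_id = "r1"), ce)
  expect_equal(unname(one$targets["p", ]), unname(nmv["r1", ]))
  two <- peptide_cell_targets(data.frame(peptide_id = "p",
                                         receptor_id = c("r1", "r2")), ce)
  expect_equal(unname(two$targets["p", ]), unname(nmv["r1", ] + nmv["r2", ]))
  # split/merge additivity
  split_a <- peptide_cell_targets(data.frame(peptide_id = "p", receptor_id = "r2"), ce)
  expect_equal(two$targets["p", ], one$targets["p", ] + split_a$targets["p", ])
  # missing receptors are reported, zero rows kept
  expect_warning(
    miss <- peptide_cell_targets(data.frame(peptide_id = c("p", "q"),
                                            receptor_id = c("r1", "nope")), ce),
    "absent")
  expect_equal(nrow(miss$missing_receptors), 1L)
  expect_equal(unname(miss$targets["q", ]), c(0, 0, 0))
})
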