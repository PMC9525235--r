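toy_receptor <- function(id = "r1", seg_res = "L", n_seg = 7) {
  seq <- paste(rep(paste0(strrep("A", 3), strrep(seg_res, 5)), n_seg),
               collapse = "")
  segs <- data.frame(start = (seq_len(n_seg) - 1) * 8 + 3,
                     end = (seq_len(n_seg) - 1) * 8 + 8)
  receptor_model(id, seq, segs)
}

test_that("peptide descriptors reduce to z-scale lookups on constant sequences", {
  z <- z_scales()
  v <- peptide_descriptor("AAAAAA")
  expect_equal(unname(v[1:5]), unname(z["A", ]))
  expect_equal(unname(v[6:20]), rep(unname(z["A", ]), 3))
  expect_equal(unname(v[["length"]]), 6)
  expect_equal(unname(v[["amidated"]]), 0)
  expect_length(v, 37)
})

test_that("amidation toggles exactly one descriptor coordinate", {
  a <- peptide_descriptor(peptidoform("ARVYKGYNGGNRVWY", c_amidated = TRUE))
  b <- peptide_descriptor(peptidoform("ARVYKGYNGGNRVWY", c_amidated = FALSE))
  d <- which(a != b)
  expect_equal(names(a)[d], "amidated")
})

test_that("the VWYa representative descriptor matches a hand lookup-and-average", {
  # independent aggregation: explicit per-position lookups over the z table
  z <- z_scales()
  s <- "ARVYKGYNGGNRVWY"
  chars <- strsplit(s, "")[[1]]
  manual_mean <- Reduce(`+`, lapply(chars, function(ch) z[ch, ])) / nchar(s)
  v <- peptide_descriptor(peptidoform(s, c_amidated = TRUE))
  expect_equal(unname(v[1:5]), unname(manual_mean))
  expect_equal(unname(v[6:10]), unname(z["A", ]))   # N-terminal 1
  expect_equal(unname(v[11:15]), unname(z["R", ]))  # N-terminal 2
  expect_equal(unname(v[31:35]), unname(z["Y", ]))  # C-terminal 3
  expect_equal(unname(v[36]), 15)
  expect_equal(unname(v[37]), 1)
  expect_error(peptide_descriptor("AG"), "length >= 3")
})

test_that("receptor descriptors are per-segment means, sensitive to segment order", {
  r <- toy_receptor()
  v <- receptor_descriptor(r)
  expect_length(v, 35)
  z <- z_scales()
  expect_equal(unname(v), rep(unname(z["L", ]), 7))
  # permuting two segments changes the vector
  r2 <- toy_receptor()
  r2$sequence <- paste0("AAAWWWWW", substr(r2$sequence, 9, nchar(r2$sequence)))
  v2 <- receptor_descriptor(r2)
  expect_false(isTRUE(all.equal(v, v2)))
  expect_equal(unname(v2[1:5]), unname(z["W", ]))
  # short receptors are refused
  expect_error(receptor_descriptor(toy_receptor(n_seg = 2)), "exactly 7")
})

test_that("the linearized outer product flattens row-major", {
  expect_equal(linearized_outer_product(c(1, 2), c(3, 4)), c(3, 4, 6, 8))
  expect_equal(linearized_outer_product(c(1, 2, 3), c(0, 0)), rep(0, 6))
  set.seed(51)
  p <- rnorm(5)
  r <- rnorm(7)
  f <- linearized_outer_product(p, r)
  for (i in 1:5) for (j in 1:7) {
    expect_equal(f[(i - 1) * 7 + j], p[i] * r[j])
  }
})

test_that("seven-TM filtering keeps exactly the full-length receptors", {
  recs <- list(a = toy_receptor("a", n_seg = 5), b = toy_receptor("b", n_seg = 7),
               c = toy_receptor("c", n_seg = 7), d = toy_receptor("d", n_seg = 6))
  expect_equal(names(filter_seven_tm(recs)), c("b", "c"))
  expect_length(filter_seven_tm(list()), 0)
})

test_that("shuffle negatives exclude positives, hit the requested count, and are seeded", {
  pos <- data.frame(peptide_id = c("p1", "p2"), receptor_id = c("r1", "r2"))
  neg <- generate_negatives(pos, ratio = 1, seed = 7)
  expect_equal(nrow(neg), 2L)
  expect_true(all(paste(neg$peptide_id, neg$receptor_id) %in%
                    c("p1 r2", "p2 r1")))
  expect_identical(generate_negatives(pos, 1, seed = 7),
                   generate_negatives(pos, 1, seed = 7))
  # ratio 1 on many positives: exact count, no overlap
  set.seed(52)
  pos2 <- unique(data.frame(peptide_id = sample(paste0("p", 1:30), 100, TRUE),
                            receptor_id = sample(paste0("r", 1:30), 100, TRUE)))
  neg2 <- generate_negatives(pos2, ratio = 1, seed = 8)
  expect_equal(nrow(neg2), nrow(pos2))
  expect_length(intersect(paste(neg2$peptide_id, neg2$receptor_id),
                          paste(pos2$peptide_id, pos2$receptor_id)), 0)
  expect_error(generate_negatives(pos, ratio = 10, seed = 1), "only")
})

test_that("training on a separable toy reaches accuracy 1 with calibrated scores", {
  set.seed(53)
  n <- 40
  x <- matrix(rnorm(n * 6, sd = 0.1), n)
  x[1:(n / 2), 1] <- x[1:(n / 2), 1] + 2
  x[(n / 2 + 1):n, 1] <- x[(n / 2 + 1):n, 1] - 2
  y <- rep(c("interact", "non_interact"), each = n / 2)
  m <- train_cpi_model(x, y, seed = 1)
  sc <- score_pairs(m, x)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(mean((sc >= 0.5) == (y == "interact")), 1)
  expect_error(train_cpi_model(x, rep("interact", n)), "both classes")
  # deterministic under a fixed seed
  m2 <- train_cpi_model(x, y, seed = 1)
  expect_equal(score_pairs(m2, x), sc)
})

test_that("pair prediction is threshold-consistent and order-invariant", {
  set.seed(54)
  peps <- list(pA = peptidoform("ARVYKGYNGGNRVWY", c_amidated = TRUE),
               pB = peptidoform("IGSDIKLVPGAGGNPW", c_amidated = TRUE),
               pC = peptidoform("QLDKSFWGHR"))
  recs <- list(rA = toy_receptor("rA", "L"), rB = toy_receptor("rB", "F"),
               rC = toy_receptor("rC", "V"))
  pairs <- expand.grid(peptide_id = names(peps), receptor_id = names(recs),
                       stringsAsFactors = FALSE)
  feats <- build_cpi_features(peps, recs, pairs)
  y <- rep(c("interact", "non_interact", "interact"), 3)
  m <- train_cpi_model(feats, y, seed = 2)
  out <- predict_pairs(m, peps, recs, threshold = 0)
  expect_equal(nrow(out$predicted), 9L)
  out_hi <- predict_pairs(m, peps, recs, threshold = 1.01)
  expect_equal(nrow(out_hi$predicted), 0L)
  out_rev <- predict_pairs(m, rev(peps), rev(recs), threshold = 0)
  key <- function(df) df$score[order(df$peptide_id, df$receptor_id)]
  expect_equal(key(out_rev$scores), key(out$scores))
  expect_error(predict_pairs(m, peps, list(x = toy_receptor("x", n_seg = 5))),
               "full-length")
})

test_that("representative choice follows the nested-longest rule, else the medoid", {
  expect_equal(choose_representative(c("NPW", "GNPW", "GGNPW")), "GGNPW")
  expect_equal(choose_representative("SINGLE"), "SINGLE")
  # designed medoid: four similar sequences and one outlier; the medoid of
  # the main group minimizes summed edit distance (verified exhaustively)
  fam <- c("AKLMNPQRST", "AKLMNPQRSW", "AKLMNPQVST", "AKLMNPQRSV",
           "GGGGGGGGGG")
  reps <- choose_representative(fam)
  d <- utils::adist(fam)
  grp_main <- 1:4
  tot <- rowSums(d[grp_main, grp_main])
  expect_true(fam[grp_main][which.min(tot)] %in% reps)
  expect_lte(length(reps), 2L)
})

test_that("receptor assignment is an injective argmax with per-peptide truncation", {
  # one peptide, seven receptors: top five kept
  sc <- data.frame(peptide_id = "p1", receptor_id = paste0("r", 1:7),
                   score = seq(0.9, 0.3, by = -0.1))
  out <- assign_receptors(sc)
  expect_equal(nrow(out), 5L)
  expect_equal(out$receptor_id, paste0("r", 1:5))
  # a receptor goes only to its argmax peptide
  sc2 <- data.frame(peptide_id = c("A", "B"), receptor_id = "r1",
                    score = c(0.9, 0.8))
  out2 <- assign_receptors(sc2)
  expect_equal(out2$peptide_id, "A")
  expect_equal(nrow(out2), 1L)
})

test_that("assignment matches a brute-force argmax + truncation oracle on random grids", {
  set.seed(55)
  for (rep in 1:5) {
    grid <- expand.grid(peptide_id = paste0("p", 1:6),
                        receptor_id = paste0("r", 1:10),
                        stringsAsFactors = FALSE)
    grid$score <- runif(nrow(grid))
    out <- assign_receptors(grid, max_per_peptide = 5)
    # oracle: per receptor argmax, then per peptide sort and head(5)
    oracle <- do.call(rbind, lapply(split(grid, grid$receptor_id), function(df) {
      df[which.max(df$score), ]
    }))
    kept <- do.call(rbind, lapply(split(oracle, oracle$peptide_id), function(df) {
      head(df[order(-df$score), ], 5)
    }))
    expect_setequal(paste(out$peptide_id, out$receptor_id),
                    paste(kept$peptide_id, kept$receptor_id))
    expect_lte(max(table(out$receptor_id)), 1L)  # receptor-side injectivity
    expect_lte(max(table(out$peptide_id)), 5L)
  }
})

test_that("descriptor-pair feature invariant holds on random vectors", {
  set.seed(56)
  for (rep in 1:20) {
    p <- rnorm(sample(2:8, 1))
    r <- rnorm(sample(2:8, 1))
    f <- linearized_outer_product(p, r)
    expect_length(f, length(p) * length(r))
    i <- sample(length(p), 1)
    j <- sample(length(r), 1)
    expect_equal(f[(i - 1) * length(r) + j], p[i] * r[j])
  }
})
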