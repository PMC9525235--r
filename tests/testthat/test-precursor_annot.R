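test_that("peptides map to exact occurrences, with misses reported", {
  prec <- "MAAAKRGGNPWGKRSSS"
  m <- map_peptides(prec, c("NPW", "ZZZ" = "QQQ"))
  expect_equal(m$spans$start[m$spans$peptide == "NPW"], 8L)
  expect_equal(m$spans$end[m$spans$peptide == "NPW"], 11L)
  expect_equal(m$misses, "QQQ")
  # two (overlapping) occurrences are both reported
  m2 <- map_peptides("AAWAWAWAA", "AWA")
  expect_equal(nrow(m2$spans), 3L)
  m3 <- map_peptides("QQNPWQQNPWQQ", "NPW")
  expect_equal(m3$spans$start, c(2L, 7L))
})

test_that("planted copy numbers are recovered exactly", {
  set.seed(31)
  cfg <- gen_config(seed = 31, n_precursors = 20)
  g <- gen_precursors(cfg)
  counts <- table(g$manifest$peptides$precursor_id)
  for (id in names(counts)) {
    pep <- g$manifest$peptides$peptide[g$manifest$peptides$precursor_id == id][1]
    expect_equal(nrow(map_peptides(g$fasta[[id]], pep)$spans),
                 as.integer(counts[[id]]))
  }
})

test_that("cleavage sites are classified by residue class on both sides", {
  # N-terminal KR site, C-terminal ED site, no amidation
  ann <- precursor_annotation("t1", "MAAKRLLNPFEDAAA", "LLNPF", amidated = FALSE)
  ann <- classify_sites(ann)
  cs <- ann$cleavage_sites
  expect_equal(cs$site_residues[cs$side == "n_terminal"], "KR")
  expect_equal(cs$cls[cs$side == "n_terminal"], "basic")
  expect_equal(cs$site_residues[cs$side == "c_terminal"], "ED")
  expect_equal(cs$cls[cs$side == "c_terminal"], "acidic")
})

test_that("the amide-donor glycine is skipped when extracting the C-terminal site", {
  # manual index arithmetic: span [4,9) holds LLNPF, then G donor, then KR
  prec <- "MAKRLLNPFGKRAA"
  ann <- classify_sites(precursor_annotation("t2", prec, "LLNPF", amidated = TRUE))
  cs <- ann$cleavage_sites
  expect_equal(cs$site_residues[cs$side == "c_terminal"], "KR")
  expect_equal(cs$position[cs$side == "c_terminal"], 10L)
  # non-amidated form reads the site from the G itself
  ann2 <- classify_sites(precursor_annotation("t3", prec, "LLNPF", amidated = FALSE))
  expect_equal(ann2$cleavage_sites$site_residues[
    ann2$cleavage_sites$side == "c_terminal"], "GK")
})

test_that("mixed and other site classes follow the residue-class definition", {
  ann <- classify_sites(precursor_annotation("t4", "AAKELLNPFSTAA", "LLNPF"))
  cs <- ann$cleavage_sites
  expect_equal(cs$cls[cs$side == "n_terminal"], "mixed")   # K + E
  expect_equal(cs$cls[cs$side == "c_terminal"], "other")   # S + T
})

test_that("spans at sequence boundaries yield absent sites, not fabricated ones", {
  ann <- classify_sites(precursor_annotation("t5", "LLNPFKR", "LLNPF"))
  cs <- ann$cleavage_sites
  expect_true(is.na(cs$site_residues[cs$side == "n_terminal"]))
  expect_equal(cs$site_residues[cs$side == "c_terminal"], "KR")
  ann2 <- classify_sites(precursor_annotation("t6", "KRLLNPF", "LLNPF"))
  expect_true(is.na(ann2$cleavage_sites$site_residues[
    ann2$cleavage_sites$side == "c_terminal"]))
})

test_that("amide donors are detected and inconsistencies reported", {
  ann <- precursor_annotation("t7", "AAKRLLNPFGKR", "LLNPF", amidated = TRUE)
  d <- detect_amide_donor(ann)
  expect_true(d$donor)
  expect_equal(nrow(d$inconsistencies), 0L)
  ann2 <- precursor_annotation("t8", "AAKRLLNPFAKR", "LLNPF", amidated = TRUE)
  d2 <- detect_amide_donor(ann2)
  expect_false(d2$donor)
  expect_equal(nrow(d2$inconsistencies), 1L)
})

test_that("planted amide-donor fractions are recovered from generated precursors", {
  cfg <- gen_config(seed = 32, n_precursors = 60, amidated_fraction = 0.5)
  g <- gen_precursors(cfg)
  rec <- annotation_recovery(g$fasta, g$manifest)
  expect_equal(rec$donor_recovery, 1)
  planted_frac <- mean(g$manifest$peptides$donor)
  expect_lt(abs(planted_frac - 0.5), 0.25)
})

test_that("pyroglutamation flags require Q/E start plus the carried delta", {
  peps <- list(peptidoform("QLDW", n_pyroglu = TRUE),
               peptidoform("ELDW", n_pyroglu = TRUE),
               peptidoform("QLDW"),
               peptidoform("ALDW"))
  expect_equal(detect_pyroglu(peps), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("single-junction context counts are exact", {
  # junction AAAAAAKR| : flank of six A, site K at -2, R at -1
  ann <- precursor_annotation("t9", "AAAAAAKRLLNPFW", "LLNPFW")
  ctx <- cleavage_context(list(ann))
  cm <- ctx$n_terminal
  expect_equal(unname(cm$counts["R", "-1"]), 1L)
  expect_equal(unname(cm$counts["K", "-2"]), 1L)
  expect_equal(unname(colSums(cm$counts[, paste0(-8:-3)])),
               rep(1L, 6), ignore_attr = TRUE)
  expect_equal(unname(cm$counts["A", "-3"]), 1L)
  # frequencies of two identical junctions equal the single-junction case
  ctx2 <- cleavage_context(list(ann, ann))
  expect_equal(ctx2$n_terminal$frequencies, cm$frequencies)
})

test_that("context windows are padded at the precursor edge and columns sum to one", {
  ann <- precursor_annotation("t10", "KRLLNPFW", "LLNPFW")  # only 2 left residues
  ctx <- cleavage_context(list(ann))
  cm <- ctx$n_terminal
  expect_equal(sum(cm$counts[, "-8"]), 0L)  # padded, excluded from counts
  expect_equal(unname(colSums(cm$frequencies)[c("-2", "-1")]), c(1, 1))
  # no junctions at all -> zero-column-sum matrices
  lone <- precursor_annotation("t11", "LLNPFW", "LLNPFW")
  ctx0 <- cleavage_context(list(lone))
  expect_equal(sum(ctx0$n_terminal$counts), 0L)
})

test_that("context frequencies are invariant to annotation order and sum to 1", {
  cfg <- gen_config(seed = 33, n_precursors = 15)
  g <- gen_precursors(cfg)
  rec <- annotation_recovery(g$fasta, g$manifest)
  anns <- rec$annotations
  ctx_a <- cleavage_context(anns)
  ctx_b <- cleavage_context(rev(anns))
  expect_equal(ctx_a$n_terminal$frequencies, ctx_b$n_terminal$frequencies)
  expect_equal(ctx_a$c_terminal$frequencies, ctx_b$c_terminal$frequencies)
  sums <- colSums(ctx_a$c_terminal$frequencies)
  expect_true(all(abs(sums[sums > 0] - 1) < 1e-9))
})

test_that("classify_sites never reads outside the precursor (fuzzed termini)", {
  set.seed(34)
  for (i in 1:25) {
    pep <- random_peptide(sample(3:6, 1))
    left <- random_peptide(sample(0:3, 1))
    right <- random_peptide(sample(0:3, 1))
    prec <- paste0(left, pep, right)
    expect_silent(classify_sites(precursor_annotation("f", prec, pep)))
  }
})

test_that("the context matrix geometry is configurable", {
  ann <- precursor_annotation("t12", "AAAAAAKRLLNPFW", "LLNPFW")
  ctx <- cleavage_context(list(ann), site_len = 2, flank_len = 2)
  expect_equal(colnames(ctx$n_terminal$counts), c("-4", "-3", "-2", "-1"))
})
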