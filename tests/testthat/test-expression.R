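# fragment counting, FPKM, rank tests, Bonferroni, contrasts

write_reads_sam <- function(path, reads, seqlen = 100000L,
                            target = "chr") {
  write_sam(reads, setNames(seqlen, target), path)
}

test_that("fragments count once per overlapping locus", {
  loci <- data.frame(id = "L1", target = "chr", start = 1000L, end = 2000L)
  reads <- data.frame(
    qname = paste0("r", 1:12), target = "chr",
    pos = c(seq(1100, 1900, by = 100), 1999L, 990L, 5000L),
    seq = strrep("A", 50), stringsAsFactors = FALSE)
  sam <- tempfile(fileext = ".sam")
  write_reads_sam(sam, reads)
  cf <- count_fragments(sam, loci)
  # 9 inside + straddling 3' boundary + straddling 5' boundary = 11
  expect_equal(unname(cf$counts), 11L)
  expect_equal(cf$library_size, 12L)
})

test_that("headerless or unsorted SAM is an input error", {
  bad <- tempfile(fileext = ".sam")
  writeLines(c("r1\t0\tchr\t10\t60\t5M\t*\t0\t0\tACGTA\t*"), bad)
  expect_error(count_fragments(bad, data.frame(id = "L", target = "chr",
                                               start = 0L, end = 10L)),
               "headered")
  unsorted <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr\tLN:1000"),
             unsorted)
  expect_error(count_fragments(unsorted, data.frame(id = "L",
                                                    target = "chr",
                                                    start = 0L, end = 10L)),
               "sorted")
})

test_that("FPKM arithmetic and the conservation identity hold", {
  expect_equal(fpkm(100, 2000, 1e6), 50)
  expect_equal(fpkm(0, 2000, 1e6), 0)
  expect_error(fpkm(1, 0, 1e6), "locus length")
  expect_error(fpkm(1, 100, 0), "library")
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(3:20, 1)
    counts <- rpois(n, 50)
    lens <- sample(500:5000, n)
    lib <- sum(counts) + rpois(1, 1000)
    f <- fpkm(counts, lens, lib)
    expect_equal(sum(f * (lens / 1000) * (lib / 1e6)), sum(counts),
                 tolerance = 1e-9)
  }
})

test_that("identical groups give p = 1; the textbook exact case gives 0.1", {
  expect_equal(rank_test(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(rank_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
})

test_that("exact branch agrees with the enumeration oracle for n <= 8", {
  set.seed(62)
  for (rep in 1:30) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    a <- sample(1:6, na, replace = TRUE)   # ties included
    b <- sample(1:6, nb, replace = TRUE)
    expect_equal(rank_test(a, b), enum_ranksum_oracle(a, b),
                 info = sprintf("rep %d", rep))
  }
  # against R's exact Mann-Whitney when there are no ties
  for (rep in 1:10) {
    a <- sample(seq(1, 100, by = 7), 4)
    b <- sample(seq(2, 100, by = 7), 4)
    expect_equal(rank_test(a, b),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("paired branch matches enumeration and handles zero diffs", {
  set.seed(63)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    a <- rnorm(n); b <- a + rnorm(n)
    expect_equal(rank_test(a, b, paired = TRUE),
                 enum_signedrank_oracle(a - b))
  }
  expect_warning(p <- rank_test(c(1, 2, 3), c(1, 2, 3), paired = TRUE),
                 "zero")
  expect_equal(p, 1)
})

test_that("large-sample branch approximates the exact p", {
  set.seed(64)
  a <- rnorm(12); b <- rnorm(12, 1)
  p_norm <- rank_test(a, b)
  p_ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_equal(p_norm, p_ref, tolerance = 1e-6)
})

test_that("Bonferroni identities hold and respect families", {
  expect_equal(bonferroni(c(0.01, 0.02)), c(0.02, 0.04))
  expect_equal(bonferroni(c(0.9, 0.5, 0.5), rep("f", 3))[1], 1)  # capped
  expect_equal(bonferroni(0.03), 0.03)          # singleton family
  p <- c(0.01, 0.04, 0.02)
  fam <- c("x", "x", "y")
  adj <- bonferroni(p, fam)
  expect_equal(adj, c(0.02, 0.08, 0.02))
  expect_true(all(adj >= p))
  # invariance to within-family order
  o <- c(2, 1, 3)
  expect_equal(bonferroni(p[o], fam[o]), adj[o])
})

test_that("grouped contrasts pick the right test branch and recover effects", {
  set.seed(65)
  mk <- function(cond, shift, n) data.frame(
    locus = paste0("L", 1:6), condition = cond,
    pair = paste0("p", rep(1:n, each = 6))[1:(6 * n)][1:(6 * n)],
    motif_class = rep(c("DTGAD", "other"), 3),
    fpkm = rexp(6 * n) + shift, stringsAsFactors = FALSE)
  recs <- rbind(
    do.call(rbind, lapply(1:8, function(i)
      transform(mk("case", 4, 1), pair = paste0("p", i)))),
    do.call(rbind, lapply(1:8, function(i)
      transform(mk("control", 0, 1), pair = paste0("p", i)))))
  res <- contrast_by_group(recs, "motif_class", c("case", "control"))
  expect_equal(unique(res$test), "mann_whitney_u")
  expect_true(all(res$p_adjusted >= res$p))
  expect_lt(min(res$p_adjusted), 0.05)
  res_p <- contrast_by_group(recs, "motif_class", c("case", "control"),
                             paired = TRUE, pairing_col = "pair")
  expect_equal(unique(res_p$test), "wilcoxon_signed_rank")
  expect_error(contrast_by_group(recs, "motif_class",
                                 c("case", "control"), paired = TRUE),
               "pairing")
})

test_that("gag co-expression flag is monotone in the threshold", {
  refs <- small_refs()
  gag_aa <- substr(ref_protein_alignment(refs)[[1]], 1, 180)
  gag_nt <- substr(refs$sequences[[1]], 1, 540)
  set.seed(66)
  reads_gag <- substring(gag_nt, seq(1, 441, by = 110),
                         seq(100, 540, by = 110))
  reads_bg <- replicate(5, random_dna(100))
  expect_true(gag_coexpression(reads_gag, gag_aa))
  expect_false(gag_coexpression(reads_bg, gag_aa))
  flags <- vapply(c(20, 60, 120, 400), function(th)
    isTRUE(gag_coexpression(reads_gag, gag_aa,
                            search_params(min_score = th))), logical(1))
  expect_true(all(diff(as.integer(flags)) <= 0))
})
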