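# translated search, frame-hit merging, flush extension, profile scan

smat_test <- ervscan:::search_matrix("BLOSUM62", -10)
empty_hits_df <- function() ervscan:::empty_hits()

test_that("a verbatim encoding yields a full self-match at diagonal score", {
  set.seed(1)
  q <- random_protein(40)
  nt <- paste(vapply(strsplit(q, "")[[1]], function(a)
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a][1],
    character(1)), collapse = "")
  h <- translated_search(nt, q, search_params(min_score = 20))
  expect_equal(nrow(h), 1L)
  expect_equal(h$qstart, 0L)
  expect_equal(h$qend, 40L)
  expect_equal(h$start, 0L)
  expect_equal(h$end, 120L)
  diag_score <- sum(diag(smat_test)[strsplit(q, "")[[1]]])
  expect_equal(h$score, diag_score)
})

test_that("reverse complement gives the same score on the minus strand", {
  set.seed(2)
  q <- random_protein(30)
  nt <- paste0(random_dna(33), paste(vapply(strsplit(q, "")[[1]],
    function(a) names(Biostrings::GENETIC_CODE)[
      Biostrings::GENETIC_CODE == a][1], character(1)), collapse = ""),
    random_dna(21))
  hp <- translated_search(nt, q, search_params(min_score = 20))
  hm <- translated_search(ervscan:::revcomp(nt), q,
                          search_params(min_score = 20))
  expect_equal(hp$score, hm$score)
  expect_setequal(hm$strand, setdiff(c("+", "-"), hp$strand))
  # plus-strand interval mirrors through the sequence length
  expect_equal(sort(c(hm$start, hm$end)),
               sort(nchar(nt) - c(hp$end, hp$start)))
})

test_that("top hit equals the brute-force Smith-Waterman oracle per frame", {
  set.seed(3)
  params <- search_params(min_score = -Inf)
  for (rep in 1:6) {
    nt <- random_dna(240)
    q <- random_protein(35)
    hits <- translated_search(nt, q, params)
    best_by_frame <- vapply(c("+", "-"), function(st) {
      s <- if (st == "+") nt else ervscan:::revcomp(nt)
      max(vapply(0:2, function(fr)
        sw_score_oracle(q, oracle_translate(s, fr), smat_test), numeric(1)))
    }, numeric(1))
    for (st in c("+", "-")) {
      hs <- hits[hits$strand == st, ]
      expect_equal(max(hs$score), unname(best_by_frame[st]),
                   info = paste("strand", st, "rep", rep))
    }
  }
})

test_that("stop codons score the configured penalty", {
  q <- "MMMMM"
  nt <- "ATGATGTAAATGATG"  # M M * M M
  h <- translated_search(nt, q, search_params(min_score = 5))
  # best local alignment must not profit from crossing the stop
  expect_true(all(h$score <= 2 * diag(smat_test)[["M"]]))
})

test_that("frame-split hits merge across a small gap (worked example)", {
  hits <- data.frame(
    target = "t", start = c(100L, 251L), end = c(250L, 400L),
    strand = "+", frame = c("0", "2"), qstart = c(0L, 48L),
    qend = c(50L, 98L), score = c(60, 55), query = "q",
    stringsAsFactors = FALSE)
  m <- merge_frame_hits(hits, search_params())
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 100L)
  expect_equal(m$end, 400L)
  expect_equal(m$frame, "mixed")
  expect_equal(m$score, 115)
})

test_that("merging is an identity on single hits and idempotent", {
  h <- data.frame(target = "t", start = 10L, end = 40L, strand = "+",
                  frame = "1", qstart = 0L, qend = 10L, score = 30,
                  query = "q", stringsAsFactors = FALSE)
  expect_equal(merge_frame_hits(h, search_params()), h)
  expect_equal(nrow(merge_frame_hits(empty_hits_df(), search_params())), 0L)
})

test_that("opposite strands never merge; merged partition matches closure", {
  set.seed(4)
  params <- search_params(merge_gap = 100)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    starts <- sample(0:2000, n)
    hits <- data.frame(
      target = "t", start = starts, end = starts + sample(30:300, n,
                                                          replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      frame = as.character(sample(0:2, n, replace = TRUE)),
      qstart = sample(0:80, n, replace = TRUE), score = 10, query = "q",
      stringsAsFactors = FALSE)
    hits$qend <- hits$qstart + sample(10:40, n, replace = TRUE)
    m <- merge_frame_hits(hits, params)
    pred <- function(i, j) ervscan:::hits_mergeable(hits[i, ], hits[j, ],
                                                    params$merge_gap)
    comp <- closure_oracle(n, pred)
    expect_equal(nrow(m), length(unique(comp)))
    # order independence
    perm <- sample(n)
    m2 <- merge_frame_hits(hits[perm, ], params)
    expect_equal(m[order(m$start), c("start", "end", "score")],
                 m2[order(m2$start), c("start", "end", "score")],
                 ignore_attr = TRUE)
    # no merge across strands
    for (grp in split(seq_len(n), comp))
      expect_length(unique(hits$strand[grp]), 1L)
  }
})

test_that("flush extension does the 3x arithmetic and clips at bounds", {
  hit <- data.frame(target = "t", start = 1000L, end = 1258L, strand = "+",
                    frame = "0", qstart = 10L, qend = 96L, score = 100,
                    query = "q", stringsAsFactors = FALSE)
  ext <- flush_extend(hit, 106L, 100000L)
  expect_equal(ext$start, 970L)
  expect_equal(ext$end, 1288L)
  expect_false(ext$clipped)
  # already flush: unchanged
  hit2 <- transform(hit, qstart = 0L, qend = 106L)
  ext2 <- flush_extend(hit2, 106L, 100000L)
  expect_equal(ext2$start, 1000L)
  expect_equal(ext2$end, 1258L)
  # clipped at the contig start
  hit3 <- transform(hit, start = 20L, end = 278L)
  ext3 <- flush_extend(hit3, 106L, 100000L)
  expect_equal(ext3$start, 0L)
  expect_true(ext3$clipped)
  # never shrinks
  expect_lte(ext$start, hit$start)
  expect_gte(ext$end, hit$end)
  # minus strand mirrors the arithmetic
  hitm <- transform(hit, strand = "-")
  extm <- flush_extend(hitm, 106L, 100000L)
  expect_equal(extm$start, 1000L - 30L)
  expect_equal(extm$end, 1258L + 30L)
})

test_that("profile scan finds the consensus and stays quiet on noise", {
  refs <- small_refs()
  aa <- ref_protein_alignment(refs)
  pr <- substr(aa, 181, 286)
  pssm <- build_pssm(pr, kind = "RVP")
  cons <- attr(pssm, "consensus")
  nt_cons <- paste(vapply(strsplit(cons, "")[[1]], function(a)
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a][1],
    character(1)), collapse = "")
  hits <- profile_scan(nt_cons, pssm, search_params())
  expect_gte(nrow(hits), 1L)
  expect_equal(max(hits$score), sum(apply(pssm, 2, max)), tolerance = 1e-9)

  # empirical null: random windows essentially never pass the threshold
  set.seed(5)
  nulls <- replicate(300, {
    nrow(profile_scan(random_dna(nchar(nt_cons)), pssm, search_params()))
  })
  expect_lt(mean(nulls > 0), 0.01)

  # partial randomization scores between the null mean and the maximum
  set.seed(6)
  ch <- strsplit(cons, "")[[1]]
  idx <- sample(length(ch), round(0.4 * length(ch)))
  ch[idx] <- sample(AA20_T, length(idx), replace = TRUE)
  ntp <- paste(vapply(ch, function(a)
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a][1],
    character(1)), collapse = "")
  hp <- profile_scan(ntp, pssm, search_params(profile_threshold = -1e6))
  expect_lt(max(hp$score), sum(apply(pssm, 2, max)))
  expect_gt(max(hp$score), 0)
})

test_that("non-IUPAC characters are an input error", {
  expect_error(translated_search("ACGTQQ", "MA"), "non-IUPAC")
})
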