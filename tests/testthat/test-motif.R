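# motif extraction, interruption flags, activity triage

test_that("published motif survey reproduces at >= 95% with exceptions listed", {
  sc <- survey_concordance()
  expect_gte(sc$concordance, 0.95)
  expect_s3_class(sc$exceptions, "data.frame")
})

test_that("spec'd single-pair classifications hold", {
  expect_equal(classify_activity("DTGAD", "GRDLL")$activity,
               "PREDICTED_ACTIVE")
  expect_equal(classify_activity("DTGVD", "GRDLL")$activity,
               "PREDICTED_ACTIVE")
  expect_equal(classify_activity("DTGSD", "GRDLL")$activity,
               "POTENTIALLY_ACTIVE")
  expect_equal(classify_activity("HTGAD", "GRDLL")$activity,
               "PREDICTED_INACTIVE")
  expect_equal(classify_activity("DTGAD", "RRDLL")$activity,
               "PREDICTED_INACTIVE")
  # length mismatches are inactive
  expect_equal(classify_activity("DTGAD", "GHLL")$activity,
               "PREDICTED_INACTIVE")
  expect_equal(classify_activity("", "GWDLL")$activity,
               "PREDICTED_INACTIVE")
  # rule trace names the fired rules
  expect_true("canonical_pair" %in%
              classify_activity("DTGAD", "GRDLL")$trace)
  expect_error(classify_activity("DTG8D", "GRDLL"), "amino-acid")
})

test_that("moving a tolerated residue to canonical never demotes", {
  rules <- default_activity_rules()
  rank_of <- c(PREDICTED_INACTIVE = 1, POTENTIALLY_ACTIVE = 2,
               PREDICTED_ACTIVE = 3)
  tab <- ervk_motif_table()
  tab <- tab[nchar(tab$b1) == 5 & nchar(tab$c2) == 5, ]
  for (i in seq_len(nrow(tab))) {
    before <- classify_activity(tab$b1[i], tab$c2[i], rules)$activity
    for (pos in 1:5) {
      b1c <- strsplit(tab$b1[i], "")[[1]]
      b1c[pos] <- rules$b1_canonical[[pos]][1]
      after <- classify_activity(paste(b1c, collapse = ""), tab$c2[i],
                                 rules)$activity
      expect_gte(rank_of[[after]], rank_of[[before]],
                 label = sprintf("%s/%s pos %d", tab$b1[i], tab$c2[i], pos))
    }
  }
})

motif_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      refs <- small_refs()
      pr_nt <- vapply(refs$sequences, function(s) substr(s, 541, 858),
                      character(1))
      names(pr_nt) <- paste0("ref_", names(pr_nt))
      # planted variants: DTGSD motif, a gap at B1 position 4, a stop, a fs
      v_sd <- pr_nt[[1]]
      b1_nt_at <- (23 - 1) * 3 + 1
      substr(v_sd, b1_nt_at, b1_nt_at + 14) <- "GATACCGGATCTGAT"  # DTGSD
      v_stop <- pr_nt[[1]]
      substr(v_stop, 181, 183) <- "TGA"
      v_fs <- pr_nt[[1]]
      v_fs <- paste0(substr(v_fs, 1, 200), substr(v_fs, 202, nchar(v_fs)))
      seqs <- c(pr_nt, planted = v_sd, stopped = v_stop, shifted = v_fs)
      ca <- align_codon_aware(seqs)
      cache <<- list(ca = ca, refs = names(pr_nt))
    }
    cache
  }
})

test_that("motifs are extracted by consensus anchoring", {
  fx <- motif_fixture()
  calls <- extract_motifs(fx$ca, fx$refs)
  ref_calls <- calls[calls$id %in% fx$refs, ]
  expect_true(all(ref_calls$b1 == "DTGAD"))
  expect_true(all(ref_calls$c2 == "GRDLL"))
  expect_equal(calls$b1[calls$id == "planted"], "DTGSD")
  expect_equal(calls$interrupted[calls$id == "stopped"], "stop")
  expect_equal(calls$interrupted[calls$id == "shifted"], "frameshift")
  expect_equal(calls$interrupted[calls$id == "planted"], "none")
})

test_that("gaps inside a motif block shrink the motif string", {
  # handcrafted alignment (independent of aligner gap placement): two
  # reference rows and one row with a codon gap at B1 position 4
  mk_row <- function(b1) paste0("MA", b1, "KLVNGRDLLPQ")
  aa <- c(r1 = mk_row("DTGAD"), r2 = mk_row("DTGAD"),
          g1 = sub("DTGAD", "DTG-D", mk_row("DTGAD"), fixed = TRUE),
          e1 = paste0("MA", "-----", "KLVNGRDLLPQ"))
  ca <- list(ids = names(aa), aa = aa,
             events = data.frame(id = character(), type = character(),
                                 source_pos = integer(),
                                 column = integer()))
  calls <- extract_motifs(ca, c("r1", "r2"))
  expect_equal(calls$b1[calls$id == "g1"], "DTGD")
  expect_equal(calls$b1[calls$id == "e1"], "")
  expect_equal(calls$c2[calls$id == "g1"], "GRDLL")
})

test_that("anchor failure is a configuration error", {
  set.seed(51)
  junk <- setNames(replicate(4, random_dna(90)), paste0("j", 1:4))
  ca <- align_codon_aware(junk)
  expect_error(extract_motifs(ca, names(junk)), "anchor")
})

test_that("the 38-42 deletion flag needs the full block gapped", {
  fx <- motif_fixture()
  refs <- small_refs()
  base <- substr(refs$sequences[[1]], 541, 858)
  drop_block <- function(from, to) paste0(
    substr(base, 1, (from - 1) * 3), substr(base, to * 3 + 1, nchar(base)))
  seqs <- c(r1 = base, r2 = base,
            del_all = drop_block(38, 42), del_part = drop_block(38, 40))
  ca <- align_codon_aware(seqs)
  expect_true(flag_38_42_deletion(ca, "del_all", "r1"))
  expect_false(flag_38_42_deletion(ca, "del_part", "r1"))
  expect_false(flag_38_42_deletion(ca, "r2", "r1"))
})

test_that("tabulation excludes interrupted rows and conserves counts", {
  calls <- data.frame(
    id = paste0("s", 1:7),
    b1 = c("DTGAD", "DTGAD", "DTGAD", "DTGVD", "DTGSD", "DTGAD", "HTGAD"),
    c2 = c("GRDLL", "GRDLL", "GRDLL", "GRDLL", "GRDLL", "GRDLL", "GRDLL"),
    interrupted = c("none", "none", "none", "none", "none", "stop", "none"),
    stringsAsFactors = FALSE)
  tab <- tabulate_motifs(calls)
  expect_equal(sum(tab$count), 6L)   # the stopped row is excluded
  expect_equal(tab$count[1], 3L)
  expect_equal(tab$b1[1], "DTGAD")
  expect_true(all(diff(tab$count) <= 0))
  expect_equal(nrow(tabulate_motifs(calls[0, ])), 0L)
})
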