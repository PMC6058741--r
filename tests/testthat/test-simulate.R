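# synthetic-data generator: reference evolution, provirus planting, reads

test_that("zero-divergence tree reproduces the ancestor at every leaf", {
  tr <- ape::read.tree(text = "(A:0,B:0);")
  rs <- make_reference_set(tr, rng_seed = 3)
  expect_true(all(rs$sequences == default_ancestor()$nt))
})

test_that("divergence is monotone in branch length and seeded", {
  tr <- ape::read.tree(text = "(A:0,B:0.5);")
  rs <- make_reference_set(tr, rng_seed = 5)
  anc <- default_ancestor()$nt
  expect_identical(rs$sequences[["A"]], anc)
  diff_b <- sum(strsplit(rs$sequences[["B"]], "")[[1]] !=
                strsplit(anc, "")[[1]])
  expect_gt(diff_b, 0)
  rs2 <- make_reference_set(tr, rng_seed = 5)
  expect_identical(rs$sequences, rs2$sequences)
})

test_that("unlabeled leaves are a configuration error", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  tr$tip.label[2] <- ""
  expect_error(make_reference_set(tr), "clade label")
})

test_that("pairwise leaf identity rank-correlates with patristic distance", {
  tr <- default_reference_tree()
  patristic <- ape::cophenetic.phylo(tr)
  rhos <- vapply(c(11, 12, 13), function(seed) {
    rs <- make_reference_set(tr, rng_seed = seed)
    chars <- strsplit(rs$sequences, "")
    ids <- names(rs$sequences)
    pd <- c(); obs <- c()
    for (i in seq_along(ids)[-length(ids)]) for (j in seq(i + 1,
                                                          length(ids))) {
      pd <- c(pd, patristic[ids[i], ids[j]])
      obs <- c(obs, mean(chars[[ids[i]]] != chars[[ids[j]]]))
    }
    stats::cor(pd, obs, method = "spearman")
  }, numeric(1))
  expect_true(all(rhos > 0.7))
})

test_that("references keep intact open reading frames", {
  rs <- make_reference_set(rng_seed = 7)
  aa <- vapply(rs$sequences, function(s)
    as.character(Biostrings::translate(Biostrings::DNAString(s))),
    character(1))
  expect_false(any(grepl("\\*", aa)))
})

test_that("mutation-free planting encodes motifs verbatim", {
  cfg <- simulation_config(genome_length = 6e4, n_elements = 1,
                           substitution_rate = 0, stop_prob = 0,
                           fs_prob = 0, solo_ltr_prob = 0, rng_seed = 2)
  sim <- plant_proviruses(cfg, small_refs())
  pr <- sim$truth[sim$truth$kind == "PR", ]
  aa <- oracle_translate(substr(sim$genome[[1]], pr$start + 1, pr$end), 0)
  expect_identical(substr(aa, 23, 27), sim$records$b1[1])
  expect_identical(substr(aa, 87, 91), sim$records$c2[1])
})

test_that("stop injection probability one interrupts every element", {
  cfg <- simulation_config(genome_length = 2e5, n_elements = 6,
                           substitution_rate = 0, stop_prob = 1,
                           fs_prob = 0, solo_ltr_prob = 0, rng_seed = 4)
  sim <- plant_proviruses(cfg, small_refs())
  expect_true(all(sim$records$status == "stop"))
})

test_that("intact fraction matches its closed-form expectation", {
  cfg <- simulation_config(genome_length = 1.2e6, n_elements = 50,
                           substitution_rate = 0.02, stop_prob = 0.1,
                           fs_prob = 0.1, solo_ltr_prob = 0, rng_seed = 9)
  sim <- plant_proviruses(cfg, small_refs())
  n_intact <- sum(sim$records$status == "intact")
  p <- (1 - 0.1) * (1 - 0.1)
  ci <- stats::qbinom(c(0.025, 0.975), 50, p)
  expect_gte(n_intact, ci[1])
  expect_lte(n_intact, ci[2])
})

test_that("planting is deterministic and truth GFF3 round-trips", {
  cfg <- simulation_config(genome_length = 1e5, n_elements = 3,
                           rng_seed = 21)
  sim1 <- plant_proviruses(cfg, small_refs())
  sim2 <- plant_proviruses(cfg, small_refs())
  expect_identical(sim1$genome, sim2$genome)
  expect_identical(sim1$truth, sim2$truth)
  path <- tempfile(fileext = ".gff3")
  write_gff3(sim1$truth, path)
  back <- read_gff3(path)
  expect_equal(back$start, sim1$truth$start)
  expect_equal(back$end, sim1$truth$end)
  expect_equal(back$kind, sim1$truth$kind)
  expect_equal(back$id, sim1$truth$id)
})

test_that("reads land inside their locus and respect abundance ratios", {
  cfg <- simulation_config(genome_length = 8e4, n_elements = 1,
                           substitution_rate = 0, stop_prob = 0,
                           fs_prob = 0, solo_ltr_prob = 0, rng_seed = 31)
  sim <- plant_proviruses(cfg, small_refs())
  loci <- sim$records[, c("id", "target", "start", "end")]
  rr <- simulate_reads(sim$genome, loci,
                       abundance = matrix(1, 1, 1), conditions = "c",
                       library_sizes = 1000, rng_seed = 1)
  aln <- read_sam(rr$sam[[1]])
  expect_equal(nrow(aln), 1000)
  expect_true(all(aln$pos >= loci$start & aln$pos + aln$width <= loci$end))

  # two equal-length loci at 1:3 abundance
  loci2 <- data.frame(id = c("a", "b"), target = names(sim$genome),
                      start = c(1000L, 40000L), end = c(3000L, 42000L))
  rr2 <- simulate_reads(sim$genome, loci2,
                        abundance = matrix(c(1, 3), 2, 1),
                        conditions = "c", library_sizes = 10000,
                        rng_seed = 2)
  counts <- rr2$truth$count
  bt <- stats::binom.test(counts[1], sum(counts), p = 0.25)
  expect_gt(bt$p.value, 0.001)

  # zero abundance -> zero fragments; zero total -> error
  rr3 <- simulate_reads(sim$genome, loci2,
                        abundance = matrix(c(0, 1), 2, 1),
                        conditions = "c", library_sizes = 500, rng_seed = 3)
  expect_equal(rr3$truth$count[1], 0)
  expect_error(simulate_reads(sim$genome, loci2,
                              abundance = matrix(0, 2, 1),
                              conditions = "c", library_sizes = 10,
                              rng_seed = 4),
               "zero total abundance")
})

test_that("probabilities outside [0,1] are rejected", {
  expect_error(simulation_config(stop_prob = 1.2), "probabilities")
})
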