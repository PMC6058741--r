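# Synthetic-data generator: genomes with planted LTR-flanked proviruses,
# clade-structured reference libraries simulated along a known tree, and
# condition-stratified read sets with planted expression differences.
# Everything is seeded; identical configuration implies identical output.

# Provirus coding layout (codons).  The mature protease monomer is 106
# residues; the B1 active-site loop and C2 helix are placed at fixed
# positions inside it.  gag- and pol(RVT)-like segments surround it so the
# planted element carries two distinct core retroviral domains.
GAG_CODONS <- 180L
PR_CODONS <- 106L
RVT_CODONS <- 220L
PR_B1_POS <- 23:27   # residue positions of the B1 motif within the mature PR
PR_C2_POS <- 87:91   # residue positions of the C2 helix motif

GENCODE <- Biostrings::GENETIC_CODE
STOP_CODONS <- names(GENCODE)[GENCODE == "*"]
CODONS_BY_AA <- split(names(GENCODE), GENCODE)

transition_of <- c(A = "G", G = "A", C = "T", T = "C")

#' Published ERVK B1/C2 motif survey
#'
#' Frequency table of observed ERVK protease active-site (B1) and helix (C2)
#' motif pairs with their published predicted-activity class, shipped as
#' plain text.  Used as the default motif vocabulary for planted proviruses
#' and as the golden fixture for the activity classifier.
#'
#' @return data.frame with columns `count`, `b1`, `c2`, `class`.
#' @export
ervk_motif_table <- function() {
  path <- system.file("extdata", "ervk_motif_survey.tsv", package = "ervscan")
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                    colClasses = c("integer", "character", "character",
                                   "character"))
}

# sample one codon per amino acid (uniform over synonymous codons)
codons_for <- function(aa) {
  vapply(strsplit(aa, "")[[1]], function(a) {
    cands <- CODONS_BY_AA[[a]]
    if (is.null(cands)) stopf("cannot encode amino acid '%s'", a)
    cands[sample.int(length(cands), 1L)]
  }, character(1), USE.NAMES = FALSE)
}

#' Deterministic ancestral provirus coding sequence
#'
#' Builds a gag-PR-RVT-like coding region (506 codons) whose mature PR
#' carries the canonical DTGAD / GRDLL motifs at fixed positions.  The
#' sequence is generated from an internal fixed seed, so it is identical
#' across sessions.
#'
#' @return list with `nt` (coding nucleotide string), `aa` (translation),
#'   and the codon coordinates of the gag/PR/RVT segments.
#' @export
default_ancestor <- function() {
  with_rng(104729L, {
    n <- GAG_CODONS + PR_CODONS + RVT_CODONS
    aa <- sample(AA20, n, replace = TRUE,
                 prob = ifelse(AA20 %in% c("L", "A", "G", "S", "E", "K"),
                               2, 1))
    aa[GAG_CODONS + PR_B1_POS] <- c("D", "T", "G", "A", "D")
    aa[GAG_CODONS + PR_C2_POS] <- c("G", "R", "D", "L", "L")
    nt <- paste(codons_for(paste(aa, collapse = "")), collapse = "")
    list(nt = nt, aa = paste(aa, collapse = ""),
         gag_codons = seq_len(GAG_CODONS),
         pr_codons = GAG_CODONS + seq_len(PR_CODONS),
         rvt_codons = GAG_CODONS + PR_CODONS + seq_len(RVT_CODONS))
  })
}

# substitute sites of a plain (non-coding) sequence; each site mutates with
# probability `rate`; transitions twice as likely as each transversion.
mutate_plain <- function(nt, rate) {
  if (rate <= 0 || !nchar(nt)) return(nt)
  chars <- strsplit(nt, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    b <- chars[i]
    others <- setdiff(DNA_BASES, b)
    w <- ifelse(others == transition_of[[b]], 2, 1)
    chars[i] <- sample(others, 1L, prob = w)
  }
  paste(chars, collapse = "")
}

# substitute sites of a coding sequence without creating stop codons and
# without touching protected codons (1-based codon indices).
mutate_coding <- function(nt, rate, protect_codons = integer()) {
  if (rate <= 0) return(nt)
  chars <- strsplit(nt, "")[[1]]
  ncod <- length(chars) %/% 3L
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    cod_idx <- (i - 1L) %/% 3L + 1L
    if (cod_idx %in% protect_codons || cod_idx > ncod) next
    b <- chars[i]
    others <- setdiff(DNA_BASES, b)
    w <- ifelse(others == transition_of[[b]], 2, 1)
    new <- sample(others, 1L, prob = w)
    cod <- chars[(cod_idx - 1L) * 3L + 1:3]
    cod[(i - 1L) %% 3L + 1L] <- new
    if (paste(cod, collapse = "") %in% STOP_CODONS) next  # reject stop gains
    chars[i] <- new
  }
  paste(chars, collapse = "")
}

#' Default 10-clade reference tree
#'
#' A fixed, labeled phylogeny emulating the HML1-HML10 clade structure, with
#' HML1/2/4/9/10 and HML3/5/6/7/8 forming the two deep subclades.
#'
#' @return an `ape` phylo object with branch lengths.
#' @export
default_reference_tree <- function() {
  nwk <- paste0(
    "(((HML1:0.08,HML2:0.07):0.05,(HML4:0.09,(HML9:0.06,HML10:0.08):0.04)",
    ":0.05):0.10,((HML3:0.07,(HML5:0.08,HML6:0.07):0.03):0.04,",
    "(HML7:0.09,HML8:0.08):0.05):0.10);")
  ape::read.tree(text = nwk)
}

#' Simulate a labeled consensus library along a reference tree
#'
#' Evolves the ancestor coding sequence along the tree: each branch applies
#' independent per-site substitutions with probability proportional to
#' branch length (capped at 0.75), transition:transversion bias 2:1,
#' rejecting substitutions that would create an internal stop so that every
#' leaf retains intact PR/RT open reading frames.  The B1/C2 motif codons
#' are held fixed, mirroring the strong conservation of the active-site
#' loop and helix across the real clade consensa.
#'
#' @param tree `phylo` object or newick string; leaves carry clade labels.
#' @param ancestor list from [default_ancestor()] (or compatible).
#' @param rng_seed integer seed.
#' @return list with `sequences` (named nt vector, one per leaf), `labels`
#'   (data.frame id/clade), `tree`, and `ancestor`.
#' @export
make_reference_set <- function(tree = default_reference_tree(),
                               ancestor = default_ancestor(),
                               rng_seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stopf("configuration error: every tree leaf must carry a clade label")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stopf("branch lengths must be >= 0")
  ntip <- length(tree$tip.label)
  with_rng(rng_seed, {
    root <- ntip + 1L
    seqs <- list()
    seqs[[root]] <- ancestor$nt
    motif_codons <- c(GAG_CODONS + PR_B1_POS, GAG_CODONS + PR_C2_POS)
    # edges of a phylo object are ordered parent -> child; walk root-down
    ord <- order(tree$edge[, 1])
    for (e in ord) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      bl <- if (is.null(tree$edge.length)) 0 else tree$edge.length[e]
      rate <- min(0.75, bl)
      seqs[[child]] <- mutate_coding(seqs[[parent]], rate,
                                     protect_codons = motif_codons)
    }
    out <- unlist(seqs[seq_len(ntip)])
    names(out) <- tree$tip.label
    list(sequences = out,
         labels = data.frame(id = tree$tip.label, clade = tree$tip.label,
                             stringsAsFactors = FALSE),
         tree = tree, ancestor = ancestor)
  })
}

#' Simulation configuration
#'
#' The stated world for the planted-provirus generator.  Defaults match the
#' acceptance conditions: a 2-Mb genome, 50 elements at 10 percent
#' nucleotide divergence from the references, 10 percent each stop and
#' frameshift injection, 10 percent solo LTRs.
#'
#' @param genome_length genome size in bp.
#' @param n_elements number of planted elements.
#' @param ltr_length LTR length in bp.
#' @param substitution_rate per-site substitution probability applied to each
#'   element (coding region stop-free; motif codons are never mutated, the
#'   assigned motif is the element's ground truth).
#' @param indel_rate per-site indel probability in LTRs (non-coding only).
#' @param stop_prob probability an element receives a premature stop in PR.
#' @param fs_prob probability an element receives a 1-nt frameshift in PR.
#' @param solo_ltr_prob probability an element is a solo LTR.
#' @param motifs data.frame with columns `b1`, `c2` (and optionally `count`
#'   weights) from which planted motifs are drawn; defaults to the published
#'   uninterrupted vocabulary.
#' @param clades character vector of clade labels to cycle through; defaults
#'   to the reference tree leaves.
#' @param strand strand(s) for planted elements.
#' @param rng_seed integer seed.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(genome_length = 2e6, n_elements = 50,
                              ltr_length = 300,
                              substitution_rate = 0.10, indel_rate = 0,
                              stop_prob = 0.10, fs_prob = 0.10,
                              solo_ltr_prob = 0.10,
                              motifs = NULL, clades = NULL,
                              strand = "+", rng_seed = 1L) {
  probs <- c(substitution_rate, indel_rate, stop_prob, fs_prob, solo_ltr_prob)
  if (any(probs < 0 | probs > 1))
    stopf("all probabilities must lie in [0, 1]")
  if (is.null(motifs)) {
    tab <- ervk_motif_table()
    motifs <- tab[nchar(tab$b1) == 5 & nchar(tab$c2) == 5,
                  c("b1", "c2", "count")]
  }
  cfg <- list(genome_length = as.integer(genome_length),
              n_elements = as.integer(n_elements),
              ltr_length = as.integer(ltr_length),
              substitution_rate = substitution_rate,
              indel_rate = indel_rate, stop_prob = stop_prob,
              fs_prob = fs_prob, solo_ltr_prob = solo_ltr_prob,
              motifs = motifs, clades = clades, strand = strand,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Plant proviruses in a synthetic genome
#'
#' Background is i.i.d. uniform nucleotide sequence.  Each planted element
#' has 5' and 3' LTRs (identical at insertion, then mutated independently),
#' and an internal gag-PR-RVT coding region derived from the assigned
#' clade's reference sequence, with the assigned B1/C2 motifs encoded
#' verbatim at the PR motif positions.  Solo-LTR elements carry no coding
#' region.  Stop codons and 1-nt frameshift deletions are injected into the
#' PR ORF with the configured probabilities.
#'
#' @param config a [simulation_config()].
#' @param references a [make_reference_set()] result (defaults to the
#'   packaged 10-clade library under the config seed).
#' @return list with `genome` (named nt vector), `truth` (annotation table:
#'   element/LTR/PR/RT features), and `records` (one row per element:
#'   id, interval, clade, b1, c2, status).
#' @export
plant_proviruses <- function(config, references = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(references))
    references <- make_reference_set(rng_seed = config$rng_seed)
  with_rng(config$rng_seed, {
    glen <- config$genome_length
    n <- config$n_elements
    target <- "synth1"
    genome <- paste(sample(DNA_BASES, glen, replace = TRUE), collapse = "")

    cds_len <- nchar(references$sequences[[1]])
    span <- 2L * config$ltr_length + cds_len + 10L  # worst-case footprint
    # non-overlapping placement with an attempt budget
    starts <- integer(0)
    attempts <- 0L
    while (length(starts) < n) {
      attempts <- attempts + 1L
      if (attempts > 1000L * n)
        stopf("simulation error: could not place %d elements in %d bp", n, glen)
      cand <- sample.int(glen - span, 1L)
      if (!length(starts) || all(abs(cand - starts) >= span + 50L))
        starts <- c(starts, cand)
    }
    starts <- sort(starts)

    clades <- config$clades %||% references$labels$clade
    clade_of <- rep_len(clades, n)
    w <- config$motifs$count %||% rep(1, nrow(config$motifs))
    midx <- sample.int(nrow(config$motifs), n, replace = TRUE, prob = w)

    truth <- list()
    rec <- list()
    chars <- strsplit(genome, "")[[1]]
    offset_shift <- 0L
    for (i in seq_len(n)) {
      solo <- stats::runif(1) < config$solo_ltr_prob
      has_stop <- !solo && stats::runif(1) < config$stop_prob
      has_fs <- !solo && stats::runif(1) < config$fs_prob
      b1 <- config$motifs$b1[midx[i]]
      c2 <- config$motifs$c2[midx[i]]
      ltr <- paste(sample(DNA_BASES, config$ltr_length, replace = TRUE),
                   collapse = "")
      ltr5 <- mutate_plain(ltr, config$substitution_rate)
      ltr3 <- mutate_plain(ltr, config$substitution_rate)
      if (config$indel_rate > 0) {  # indels confined to non-coding LTR copies
        drop5 <- which(stats::runif(nchar(ltr5)) < config$indel_rate)
        if (length(drop5))
          ltr5 <- paste(strsplit(ltr5, "")[[1]][-drop5], collapse = "")
        drop3 <- which(stats::runif(nchar(ltr3)) < config$indel_rate)
        if (length(drop3))
          ltr3 <- paste(strsplit(ltr3, "")[[1]][-drop3], collapse = "")
      }
      status <- "intact"
      pr_rel <- NULL; rt_rel <- NULL; cds <- ""
      if (solo) {
        element <- ltr5
        status <- "solo_ltr"
      } else {
        base <- references$sequences[[clade_of[i]]]
        anc <- references$ancestor
        motif_codons <- c(GAG_CODONS + PR_B1_POS, GAG_CODONS + PR_C2_POS)
        cds <- mutate_coding(base, config$substitution_rate,
                             protect_codons = motif_codons)
        cvec <- codons_of(cds)
        cvec[GAG_CODONS + PR_B1_POS] <- codons_for(b1)
        cvec[GAG_CODONS + PR_C2_POS] <- codons_for(c2)
        if (has_stop) {
          pool <- setdiff(GAG_CODONS + seq(2L, PR_CODONS - 1L), motif_codons)
          cvec[sample(pool, 1L)] <- sample(STOP_CODONS, 1L)
          status <- "stop"
        }
        cds <- paste(cvec, collapse = "")
        if (has_fs) {
          # delete one nucleotide inside the PR ORF, outside motif codons
          pool <- setdiff(GAG_CODONS + seq(2L, PR_CODONS - 1L), motif_codons)
          cod <- sample(pool, 1L)
          pos <- (cod - 1L) * 3L + sample.int(3L, 1L)
          cds <- paste0(substr(cds, 1L, pos - 1L),
                        substr(cds, pos + 1L, nchar(cds)))
          if (status == "intact") status <- "frameshift"
        }
        pr_start_rel <- nchar(ltr5) + GAG_CODONS * 3L
        pr_len <- PR_CODONS * 3L - if (has_fs) 1L else 0L
        pr_rel <- c(pr_start_rel, pr_start_rel + pr_len)
        rt_rel <- c(nchar(ltr5) + nchar(cds) - RVT_CODONS * 3L,
                    nchar(ltr5) + nchar(cds))
        element <- paste0(ltr5, cds, ltr3)
      }
      if (identical(config$strand, "-")) element <- revcomp(element)
      s0 <- starts[i] + offset_shift
      e0 <- s0 + nchar(element)
      chars_mid <- strsplit(element, "")[[1]]
      chars <- c(chars[seq_len(s0)], chars_mid,
                 chars[seq(s0 + 1L, length(chars))])
      offset_shift <- offset_shift + nchar(element)

      id <- sprintf("elem%03d", i)
      feat <- list(annotation_table(target, s0, e0, config$strand,
                                    if (solo) "solo_LTR" else "element",
                                    "simulation", id = id,
                                    clade = clade_of[i], b1 = b1, c2 = c2,
                                    status = status))
      if (!solo) {
        feat <- c(feat, list(
          annotation_table(target, s0, s0 + nchar(ltr5), config$strand,
                           "LTR", "simulation", id = id, clade = clade_of[i],
                           b1 = "", c2 = "", status = status),
          annotation_table(target, e0 - nchar(ltr3), e0, config$strand,
                           "LTR", "simulation", id = id, clade = clade_of[i],
                           b1 = "", c2 = "", status = status),
          annotation_table(target, s0 + pr_rel[1], s0 + pr_rel[2],
                           config$strand, "PR", "simulation", id = id,
                           clade = clade_of[i], b1 = b1, c2 = c2,
                           status = status),
          annotation_table(target, s0 + rt_rel[1], s0 + rt_rel[2],
                           config$strand, "RT", "simulation", id = id,
                           clade = clade_of[i], b1 = "", c2 = "",
                           status = status)))
      }
      truth[[i]] <- do.call(rbind, feat)
      rec[[i]] <- data.frame(id = id, target = target, start = s0, end = e0,
                             clade = clade_of[i], b1 = b1, c2 = c2,
                             status = status, stringsAsFactors = FALSE)
    }
    genome <- paste(chars, collapse = "")
    truth <- do.call(rbind, truth)
    records <- do.call(rbind, rec)
    list(genome = stats::setNames(genome, target), truth = truth,
         records = records)
  })
}

codons_of <- function(nt) {
  n <- nchar(nt) %/% 3L
  substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Simulate condition-stratified read sets from planted loci
#'
#' Error-free single-end reads are drawn from loci with probability
#' proportional to abundance x locus length, placed uniformly, and written
#' as headered coordinate-sorted SAM, one file per sample.
#'
#' @param genome named nt vector (one target).
#' @param loci data.frame with columns `id`, `target`, `start`, `end`
#'   (0-based half-open).
#' @param abundance numeric matrix, loci x samples (row order = `loci`).
#' @param conditions character vector, one condition label per sample.
#' @param library_sizes integer vector of fragments per sample.
#' @param read_length read length in bp.
#' @param dir output directory for SAM files.
#' @param rng_seed integer seed.
#' @return list with `sam` (named vector of file paths) and `truth`
#'   (data.frame locus/sample/condition/expected count and FPKM).
#' @export
simulate_reads <- function(genome, loci, abundance, conditions,
                           library_sizes, read_length = 100L,
                           dir = tempfile("reads"), rng_seed = 1L) {
  stopifnot(is.matrix(abundance), nrow(abundance) == nrow(loci),
            ncol(abundance) == length(conditions),
            length(library_sizes) == length(conditions))
  if (any(abundance < 0)) stopf("abundances must be >= 0")
  if (any(library_sizes <= 0)) stopf("library sizes must be > 0")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  target <- names(genome)[1]
  glen <- nchar(genome[[1]])
  lens <- loci$end - loci$start
  with_rng(rng_seed, {
    sams <- character(ncol(abundance))
    truth <- list()
    for (s in seq_len(ncol(abundance))) {
      wt <- abundance[, s] * lens
      if (sum(wt) <= 0)
        stopf("simulation error: zero total abundance with nonzero library")
      prob <- wt / sum(wt)
      counts <- as.integer(stats::rmultinom(1, library_sizes[s], prob))
      reads <- list()
      for (l in seq_len(nrow(loci))) {
        if (counts[l] == 0) next
        hi <- max(loci$start[l], loci$end[l] - read_length)
        pos <- loci$start[l] +
          sample.int(max(1L, hi - loci$start[l] + 1L), counts[l],
                     replace = TRUE) - 1L
        pos <- pmin(pos, glen - read_length)
        reads[[l]] <- data.frame(
          qname = sprintf("s%02d_%s_r%05d", s, loci$id[l], seq_len(counts[l])),
          target = target, pos = pos,
          seq = substring(genome[[1]], pos + 1L, pos + read_length),
          stringsAsFactors = FALSE)
      }
      reads <- if (length(reads)) do.call(rbind, reads) else
        data.frame(qname = character(), target = character(),
                   pos = integer(), seq = character())
      sample_id <- sprintf("sample%02d", s)
      sams[s] <- file.path(dir, paste0(sample_id, ".sam"))
      write_sam(reads, stats::setNames(glen, target), sams[s])
      truth[[s]] <- data.frame(
        locus = loci$id, sample = sample_id, condition = conditions[s],
        count = counts,
        expected_count = prob * library_sizes[s],
        expected_fpkm = prob * 1e9 / lens,
        stringsAsFactors = FALSE)
      names(sams)[s] <- sample_id
    }
    list(sam = sams, truth = do.call(rbind, truth))
  })
}
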