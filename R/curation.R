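# Curation filters and locus grouping: gap-induction removal, short-domain
# flags, single-linkage locus clustering at 10 kb, duplicate detection, and
# alternative-assembly flank matching.

#' Remove sequences that induce gaps in most alignment rows
#'
#' A sequence is removed iff it owns an insertion column (a column where
#' the fraction of gapped rows is at least `threshold`) in which it is
#' non-gap.  The removal set is computed once against the original
#' alignment, not iteratively.
#'
#' @param alignment named character vector of aligned sequences (rows of
#'   equal length, `-` gaps).
#' @param threshold gap-induction fraction; the published rule is >= 0.95.
#' @return the retained subset of `alignment`; removed ids in attribute
#'   `removed`.
#' @export
gap_induction_filter <- function(alignment, threshold = 0.95) {
  if (length(alignment) < 2L) stopf("alignment needs at least 2 rows")
  m <- do.call(rbind, strsplit(alignment, ""))
  gapfrac <- colMeans(m == "-")
  bad_cols <- which(gapfrac >= threshold)
  removed <- logical(length(alignment))
  if (length(bad_cols))
    removed <- apply(m[, bad_cols, drop = FALSE] != "-", 1, any)
  out <- alignment[!removed]
  attr(out, "removed") <- names(alignment)[removed]
  out
}

#' Flag domain hits shorter than a fraction of the expected length
#'
#' Flagged hits are retained but annotated; flag is true iff
#' `aligned_length < fraction * expected_length` (strict).
#'
#' @param aligned_length hit length (aa), vectorized.
#' @param expected_length expected domain length (aa).
#' @param fraction threshold fraction (default one half).
#' @return logical vector.
#' @export
short_domain_flag <- function(aligned_length, expected_length,
                              fraction = 0.5) {
  if (expected_length <= 0) stopf("expected length must be > 0")
  aligned_length < fraction * expected_length
}

#' Group annotations into loci
#'
#' A locus is one or more PR/RT encoding regions on the same target
#' separated by no more than `max_gap` bp: the single-linkage clusters of
#' intervals under the end-to-start gap predicate.
#'
#' @param ann annotation data.frame (0-based half-open intervals).
#' @param max_gap maximum separation in bp (published value 10,000).
#' @return data.frame of loci (`locus`, `target`, `start`, `end`,
#'   `n_members`), with attribute `membership` mapping each input row to its
#'   locus id.
#' @export
group_loci <- function(ann, max_gap = 10000) {
  if (!nrow(ann)) {
    out <- data.frame(locus = character(), target = character(),
                      start = integer(), end = integer(),
                      n_members = integer(), stringsAsFactors = FALSE)
    attr(out, "membership") <- integer(0)
    return(out)
  }
  gr <- GenomicRanges::GRanges(ann$target,
                               IRanges::IRanges(ann$start + 1L, ann$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L,
                               with.revmap = TRUE, ignore.strand = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  membership <- integer(nrow(ann))
  for (i in seq_along(revmap)) membership[revmap[[i]]] <- i
  out <- data.frame(
    locus = sprintf("locus%04d", seq_along(red)),
    target = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    n_members = lengths(revmap), stringsAsFactors = FALSE)
  attr(out, "membership") <- membership
  out
}

#' Partition sequences into exact-identity classes
#'
#' @param sequences named character vector (names are locus/sequence ids).
#' @return data.frame `id`, `class` (integer), `representative`; classes
#'   are numbered by first appearance.
#' @export
dedupe_sequences <- function(sequences) {
  if (!length(sequences))
    return(data.frame(id = character(), class = integer(),
                      representative = character(), stringsAsFactors = FALSE))
  cls <- match(sequences, unique(sequences))
  rep_ids <- names(sequences)[match(unique(cls), cls)]
  data.frame(id = names(sequences), class = cls,
             representative = rep_ids[cls], stringsAsFactors = FALSE)
}

#' Match PR loci against alternative assembly sequences
#'
#' For each PR annotation the `flank` bp on both sides of its start site are
#' extracted from the primary genome (clipped at bounds) and compared with
#' each alternative sequence: `technical_duplicate` when the available flank
#' matches exactly (100 percent identity over >= 99 percent of the available
#' flank, clipped ends allowed); `similar_insertion_divergent_locus` when
#' the PR sequence itself matches exactly but the flank only aligns
#' partially (local alignment covering >= `partial_coverage` of the flank at
#' >= `partial_identity` identity); otherwise `novel`.
#'
#' @param pr_ann annotation data.frame of PR hits on the primary genome.
#' @param primary named nt vector (primary genome).
#' @param alternatives named nt vector of alternative assembly sequences.
#' @param flank flank size in bp (published value 15,000).
#' @param partial_coverage,partial_identity partial-match thresholds.
#' @return data.frame with one row per (PR, alternative) pair and a
#'   `verdict` column.
#' @export
match_alt_assemblies <- function(pr_ann, primary, alternatives,
                                 flank = 15000,
                                 partial_coverage = 0.2,
                                 partial_identity = 0.9) {
  genome <- primary[[1]]
  glen <- nchar(genome)
  res <- list()
  for (i in seq_len(nrow(pr_ann))) {
    s <- pr_ann$start[i]
    flank_lo <- max(0L, s - as.integer(flank))
    flank_hi <- min(glen, s + as.integer(flank))
    flank_seq <- substr(genome, flank_lo + 1L, flank_hi)
    pr_seq <- substr(genome, pr_ann$start[i] + 1L, pr_ann$end[i])
    for (a in names(alternatives)) {
      alt <- alternatives[[a]]
      verdict <- "novel"
      exact <- length(Biostrings::matchPattern(flank_seq, alt)) > 0L
      if (!exact && nchar(alt) < nchar(flank_seq)) {
        # the alternative contig may be shorter than the flank window: exact
        # if it is itself a clipped copy of the flank region
        exact <- length(Biostrings::matchPattern(alt, flank_seq)) > 0L &&
          nchar(alt) >= 0.99 * min(nchar(alt), nchar(flank_seq))
      }
      if (exact) {
        verdict <- "technical_duplicate"
      } else if (length(Biostrings::matchPattern(pr_seq, alt)) > 0L) {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(flank_seq), Biostrings::DNAString(alt),
          type = "local")
        cov <- Biostrings::nchar(pa) / nchar(flank_seq)
        ident <- Biostrings::pid(pa) / 100
        if (cov >= partial_coverage && ident >= partial_identity)
          verdict <- "similar_insertion_divergent_locus"
      }
      res[[length(res) + 1L]] <- data.frame(
        pr = rownames(pr_ann)[i] %||% as.character(i), alternative = a,
        verdict = verdict, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
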