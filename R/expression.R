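# Locus-level expression: fragment counting from SAM, FPKM normalization,
# exact/approximate rank tests, Bonferroni families, grouped contrasts and
# the gag co-expression check.

#' Count fragments per locus
#'
#' A fragment counts once toward a locus iff its primary alignment
#' overlaps the locus interval by at least 1 bp; mates of a pair count as
#' one fragment (the first-of-pair mate carries the count).
#'
#' @param sam path to a headered, coordinate-sorted SAM file.
#' @param loci data.frame with `id`, `target`, `start`, `end` (0-based
#'   half-open).
#' @return list with `counts` (named integer per locus) and `library_size`
#'   (total mapped primary fragments in the sample).
#' @export
count_fragments <- function(sam, loci) {
  aln <- read_sam(sam)
  # mates of a pair count once: keep unpaired reads and first-of-pair mates
  paired <- bitwAnd(aln$flag, 1L) != 0L
  first <- bitwAnd(aln$flag, 64L) != 0L
  frag <- aln[!paired | first, , drop = FALSE]
  lib <- nrow(frag)
  if (!nrow(loci))
    return(list(counts = integer(0), library_size = lib))
  gr_loci <- GenomicRanges::GRanges(loci$target,
                                    IRanges::IRanges(loci$start + 1L,
                                                     loci$end))
  gr_frag <- GenomicRanges::GRanges(frag$target,
                                    IRanges::IRanges(frag$pos + 1L,
                                                     frag$pos + frag$width))
  ov <- GenomicRanges::countOverlaps(gr_loci, gr_frag, minoverlap = 1L)
  list(counts = stats::setNames(as.integer(ov), loci$id),
       library_size = lib)
}

#' Fragments per kilobase of locus per million mapped fragments
#'
#' @param count fragment count (vectorized).
#' @param locus_length locus length in bp.
#' @param library_size mapped fragments in the sample.
#' @return FPKM values.
#' @export
fpkm <- function(count, locus_length, library_size) {
  if (any(locus_length <= 0)) stopf("locus length must be > 0")
  if (any(library_size <= 0)) stopf("library size must be > 0")
  count / (locus_length / 1000) / (library_size / 1e6)
}

# memoised combination index matrices for the exact null enumerations
.combn_cache <- new.env(parent = emptyenv())
combn_cached <- function(n, k) {
  key <- paste(n, k)
  got <- get0(key, envir = .combn_cache)
  if (is.null(got)) {
    got <- utils::combn(n, k)
    assign(key, got, envir = .combn_cache)
  }
  got
}

# exact null enumeration of the rank-sum statistic (ties via average ranks)
exact_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  obs <- sum(r[seq_len(na)])
  combs <- combn_cached(length(pooled), na)
  sums <- colSums(matrix(r[combs], nrow = na))
  eps <- 1e-9
  p_low <- mean(sums <= obs + eps)
  p_high <- mean(sums >= obs - eps)
  min(1, 2 * min(p_low, p_high))
}

# exact null enumeration of the signed-rank statistic
exact_signedrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- as.numeric(signs %*% r)
  eps <- 1e-9
  p_low <- mean(sums <= obs + eps)
  p_high <- mean(sums >= obs - eps)
  min(1, 2 * min(p_low, p_high))
}

#' Two-sided nonparametric rank test
#'
#' Mann-Whitney U for unpaired data, Wilcoxon signed-rank for paired data.
#' Small samples (unpaired: nA + nB <= 16; paired: n <= 12) use exact null
#' enumeration (ties handled by average ranks); larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors (equal length and pair-aligned when paired).
#' @param paired logical.
#' @return two-sided p-value.
#' @export
rank_test <- function(a, b, paired = FALSE) {
  if (paired) {
    if (length(a) != length(b)) stopf("paired test needs equal lengths")
    d <- a - b
    if (all(d == 0)) {
      warning("all paired differences are zero; p = 1")
      return(1)
    }
    d <- d[d != 0]
    n <- length(d)
    if (n <= 12L) return(exact_signedrank_p(d))
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    return(min(1, 2 * stats::pnorm(-abs(z))))
  }
  if (!length(a) || !length(b)) stopf("both groups must be nonempty")
  if (length(a) + length(b) <= 16L) return(exact_ranksum_p(a, b))
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Bonferroni adjustment within explicit families
#'
#' @param p raw p-values.
#' @param family family id per p-value (all contrasts sharing the same
#'   variable set form one family).
#' @return adjusted p-values, `min(1, p * family_size)`.
#' @export
bonferroni <- function(p, family = rep(1L, length(p))) {
  m <- stats::ave(p, family, FUN = length)
  pmin(1, p * m)
}

#' Grouped condition contrasts
#'
#' Runs one rank test per grouping cell (optionally per stratum) between
#' the two condition levels, then Bonferroni-adjusts within the family of
#' contrasts sharing the same variable set.
#'
#' @param records data.frame of expression records with columns `fpkm`,
#'   `condition`, the grouping columns, and (for paired designs) a pairing
#'   key column.
#' @param group_cols columns defining the grouping cells (e.g. clade and
#'   motif class).
#' @param condition_levels length-2 character: the two conditions compared
#'   (A vs B).
#' @param paired logical; paired designs align observations by
#'   `pairing_col` within each cell.
#' @param pairing_col pairing key column for paired designs.
#' @param strata_col optional stratification column (e.g. sex); each
#'   stratum forms its own family.
#' @return data.frame of `ContrastResult` rows: group, test, p, adjusted p,
#'   family id, group sizes.
#' @export
contrast_by_group <- function(records, group_cols, condition_levels,
                              paired = FALSE, pairing_col = NULL,
                              strata_col = NULL) {
  if (paired && is.null(pairing_col))
    stopf("paired design requires a pairing key column")
  strata <- if (is.null(strata_col)) list(records) else
    split(records, records[[strata_col]])
  out <- list()
  for (sname in names(strata) %||% "") {
    rec <- if (is.null(strata_col)) records else strata[[sname]]
    cells <- split(rec, rec[, group_cols, drop = FALSE], drop = TRUE)
    family_id <- paste(c(group_cols, strata_col,
                         if (nzchar(sname)) sname), collapse = "|")
    for (cname in names(cells)) {
      cell <- cells[[cname]]
      ga <- cell[cell$condition == condition_levels[1], , drop = FALSE]
      gb <- cell[cell$condition == condition_levels[2], , drop = FALSE]
      if (!nrow(ga) || !nrow(gb)) next
      if (paired) {
        if (anyNA(match(ga[[pairing_col]], gb[[pairing_col]])))
          stopf("missing pairing key in paired design (cell %s)", cname)
        gb <- gb[match(ga[[pairing_col]], gb[[pairing_col]]), , drop = FALSE]
        p <- rank_test(ga$fpkm, gb$fpkm, paired = TRUE)
        test <- "wilcoxon_signed_rank"
      } else {
        p <- rank_test(ga$fpkm, gb$fpkm, paired = FALSE)
        test <- "mann_whitney_u"
      }
      out[[length(out) + 1L]] <- data.frame(
        group = cname, stratum = if (nzchar(sname)) sname else NA_character_,
        test = test, p = p, family = family_id,
        n_a = nrow(ga), n_b = nrow(gb), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(group = character(), stratum = character(), test = character(),
               p = numeric(), family = character(), n_a = integer(),
               n_b = integer(), stringsAsFactors = FALSE)
  res$p_adjusted <- bonferroni(res$p, res$family)
  res
}

#' Flag gag co-expression at a locus
#'
#' TRUE iff at least `min_reads` of the reads aligned to the locus produce
#' translated-search hits to the Gag query above the score threshold.
#'
#' @param read_seqs character vector of read nucleotide sequences.
#' @param gag_query Gag protein sequence.
#' @param params a [search_params()]; `min_score` is the hit threshold
#'   (default 55: comfortably above the best chance alignment of a
#'   100-nt read's translation, far below a true gag read's score).
#' @param min_reads minimum number of supporting reads.
#' @return logical flag with attribute `n_hits`.
#' @export
gag_coexpression <- function(read_seqs, gag_query,
                             params = search_params(min_score = 55),
                             min_reads = 1L) {
  hits <- 0L
  for (s in read_seqs) {
    h <- translated_search(s, gag_query, params, target_id = "read")
    if (nrow(h)) hits <- hits + 1L
  }
  structure(hits >= min_reads, n_hits = hits)
}

#' Normality screening diagnostic (reported only, never a gate)
#'
#' @param values numeric FPKM values.
#' @return list with Shapiro-Wilk p (when computable) and quartile summary.
#' @export
normality_screen <- function(values) {
  sw <- if (length(values) >= 3 && length(unique(values)) > 1 &&
            length(values) <= 5000)
    stats::shapiro.test(values)$p.value else NA_real_
  list(shapiro_p = sw, quartiles = stats::quantile(values))
}
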