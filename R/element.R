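# LTR retroelement detection: similar direct-repeat pairs found by exact
# k-mer seeding and ungapped X-drop extension, plus the domain
# co-occurrence curation rule.

#' LTR pair finder parameters
#'
#' Defaults are LTRharvest-like scales: LTR length 100-1000 bp, pair
#' identity at least 85 percent, repeat-start separation 1-15 kb, seed
#' k-mer 12.
#'
#' @param ltr_range numeric length-2, LTR length bounds (bp).
#' @param min_identity minimum direct-repeat identity (fraction).
#' @param spacing_range numeric length-2, allowed separation between the
#'   repeat start positions (bp); the minimum must exceed the maximum LTR
#'   length so the two repeats cannot overlap.
#' @param k seed k-mer size.
#' @return list of class `ltr_params`.
#' @export
ltr_params <- function(ltr_range = c(100, 1000), min_identity = 0.85,
                       spacing_range = c(1001, 15000), k = 12L) {
  stopifnot(ltr_range[1] >= k, spacing_range[1] > ltr_range[2])
  structure(list(ltr_range = as.integer(ltr_range),
                 min_identity = min_identity,
                 spacing_range = as.integer(spacing_range), k = as.integer(k)),
            class = "ltr_params")
}

# positions (0-based) of every k-mer, grouped by k-mer integer code
kmer_positions <- function(chars, k) {
  base <- match(chars, DNA_BASES) - 1L
  n <- length(base)
  if (n < k) return(list(code = integer(0), pos = integer(0)))
  np <- n - k + 1L
  code <- numeric(np)
  for (j in seq_len(k))
    code <- code * 4 + base[seq(j, j + np - 1L)]
  ok <- !is.na(code)
  list(code = code[ok], pos = which(ok) - 1L)
}

# ungapped X-drop extension of a seed on diagonal d; returns c(start, end)
# (0-based half-open, on the first repeat copy) of the max-scoring run.
extend_seed <- function(match_vec, seed_lo, seed_hi, max_len, xdrop = 20) {
  sc <- ifelse(match_vec, 1, -3)
  best_lo <- seed_lo; cur <- 0; best <- 0
  i <- seed_lo
  while (i > 1L && (seed_hi - (i - 1L)) < max_len) {
    i <- i - 1L
    cur <- cur + sc[i]
    if (cur > best) { best <- cur; best_lo <- i }
    if (cur < best - xdrop) break
  }
  lo <- best_lo
  best_hi <- seed_hi; cur <- 0; best <- 0
  i <- seed_hi
  while (i < length(sc) && (i + 1L - lo + 1L) <= max_len) {
    i <- i + 1L
    cur <- cur + sc[i]
    if (cur > best) { best <- cur; best_hi <- i }
    if (cur < best - xdrop) break
  }
  c(lo, best_hi)
}

#' Find candidate LTR retroelements as similar direct-repeat pairs
#'
#' Exact k-mer matches at an allowed separation seed ungapped X-drop
#' extensions along the diagonal; extended repeats within the length range
#' at the identity threshold become candidate elements.  Overlapping
#' candidates are resolved by highest identity, then longest.
#'
#' @param target nucleotide sequence.
#' @param params an [ltr_params()].
#' @param target_id identifier.
#' @return data.frame of candidate elements: element interval, both LTR
#'   intervals (0-based half-open) and percent identity.
#' @export
find_ltr_pairs <- function(target, params = ltr_params(),
                           target_id = "target") {
  target <- check_dna(target, "target")
  chars <- strsplit(target, "")[[1]]
  km <- kmer_positions(chars, params$k)
  if (!length(km$pos)) return(empty_candidates())
  ord <- order(km$code, km$pos)
  code <- km$code[ord]; pos <- km$pos[ord]
  cands <- list()
  seen_diag <- new.env(hash = TRUE)
  runs <- rle(code)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (g in which(runs$lengths >= 2L)) {
    p <- pos[starts[g]:ends[g]]
    prs <- utils::combn(p, 2L)
    for (c2i in seq_len(ncol(prs))) {
      i <- prs[1, c2i]; j <- prs[2, c2i]
      d <- j - i
      if (d < params$spacing_range[1] || d > params$spacing_range[2]) next
      dkey <- as.character(d)
      done <- get0(dkey, envir = seen_diag, ifnotfound = integer(0))
      if (any(abs(done - i) <= params$ltr_range[2])) next
      assign(dkey, c(done, i), envir = seen_diag)
      # window around the seed on diagonal d, bounded by repeat length cap
      lo_lim <- max(1L, i + 1L - params$ltr_range[2])
      hi_lim <- min(length(chars) - d, i + params$ltr_range[2])
      idx <- seq(lo_lim, hi_lim)
      mv <- chars[idx] == chars[idx + d]
      seed_lo <- i + 1L - lo_lim + 1L
      res <- extend_seed(mv, seed_lo, seed_lo + params$k - 1L,
                         params$ltr_range[2])
      len <- res[2] - res[1] + 1L
      ident <- mean(mv[res[1]:res[2]])
      if (len < params$ltr_range[1] || len > params$ltr_range[2]) next
      if (ident < params$min_identity) next
      s0 <- lo_lim + res[1] - 2L             # back to 0-based genome coords
      cands[[length(cands) + 1L]] <- data.frame(
        target = target_id, start = s0, end = s0 + len + d,
        ltr5_start = s0, ltr5_end = s0 + len,
        ltr3_start = s0 + d, ltr3_end = s0 + d + len,
        identity = 100 * ident, stringsAsFactors = FALSE)
    }
  }
  if (!length(cands)) return(empty_candidates())
  out <- do.call(rbind, cands)
  # overlap resolution: highest identity, then longest
  out <- out[order(-out$identity, -(out$end - out$start)), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) for (j in seq(i + 1L, nrow(out))) {
      if (keep[j] && out$start[j] < out$end[i] && out$start[i] < out$end[j])
        keep[j] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(target = character(), start = integer(), end = integer(),
             ltr5_start = integer(), ltr5_end = integer(),
             ltr3_start = integer(), ltr3_end = integer(),
             identity = numeric(), stringsAsFactors = FALSE)
}

#' Domain co-occurrence filter
#'
#' A profile-scan domain hit is retained only when the candidate element
#' containing it also contains at least one additional core retroviral
#' domain of a different kind; standalone RVT_1 hits (LINE-like) are
#' discarded.  Hits not contained in any element are dropped.
#'
#' @param elements candidate element data.frame (from [find_ltr_pairs()] or
#'   equivalent intervals).
#' @param domain_hits annotation-style data.frame with `start`, `end`,
#'   `kind`.
#' @param core_kinds the core retroviral domain set.
#' @return the retained rows of `domain_hits` (input order preserved),
#'   with an `element` column giving the containing element index.
#' @export
cooccurrence_filter <- function(elements, domain_hits,
                                core_kinds = c("RVP", "RVT_1", "IN", "gag")) {
  if (!nrow(domain_hits) || !nrow(elements)) {
    out <- domain_hits[integer(0), , drop = FALSE]
    out$element <- integer(0)
    return(out)
  }
  elem_of <- rep(NA_integer_, nrow(domain_hits))
  for (h in seq_len(nrow(domain_hits))) {
    inside <- which(domain_hits$target[h] == elements$target &
                    domain_hits$start[h] >= elements$start &
                    domain_hits$end[h] <= elements$end)
    if (length(inside)) elem_of[h] <- inside[1]  # containment is exclusive
  }
  keep <- logical(nrow(domain_hits))
  for (h in seq_len(nrow(domain_hits))) {
    e <- elem_of[h]
    if (is.na(e) || !(domain_hits$kind[h] %in% core_kinds)) next
    partners <- which(elem_of == e & domain_hits$kind != domain_hits$kind[h] &
                      domain_hits$kind %in% core_kinds)
    keep[h] <- length(partners) > 0L
  }
  out <- domain_hits[keep, , drop = FALSE]
  out$element <- elem_of[keep]
  rownames(out) <- NULL
  out
}
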