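# Six-frame translated homology search: local alignment of a protein query
# against all six frame translations of a nucleotide target, frame-hit
# merging, flush extension, and PSSM profile scanning.

#' Search parameters
#'
#' @param matrix substitution matrix name (Biostrings data set).
#' @param gap_open,gap_extend affine gap penalties (a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @param min_score minimum alignment score to report.  The default (75) was
#'   fixed once so that 106-aa protease queries at 30 percent amino-acid
#'   divergence are recovered while random 106-aa vs window alignments stay
#'   far below it.
#' @param merge_gap maximum target gap (bp) between frame hits merged into
#'   one gene, and collinearity overlap tolerance of 5 aa.
#' @param profile_threshold minimum PSSM window score in bits.
#' @param chunk_size,chunk_overlap window size/overlap (nt) used to scan
#'   long targets; each window reports its best local alignment per frame.
#' @param prescan_min ungapped-prescan threshold (substitution-matrix
#'   units) used on targets longer than one chunk: each frame translation
#'   is scored ungapped against the query at every offset (a fast
#'   vectorized pass) and only regions reaching `prescan_min` are given to
#'   the full Smith-Waterman alignment.  Single-chunk targets are always
#'   aligned exactly (no prescan); that is the path checked against the
#'   Smith-Waterman oracle.
#' @param stop_score alignment score of the stop symbol against everything.
#' @return list of class `search_params`.
#' @export
search_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          min_score = 75, merge_gap = 1000,
                          profile_threshold = 30,
                          chunk_size = 12000L, chunk_overlap = 3000L,
                          prescan_min = 40, stop_score = -10) {
  stopifnot(gap_open >= 0, gap_extend >= 0, merge_gap >= 0)
  p <- list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
            min_score = min_score, merge_gap = merge_gap,
            profile_threshold = profile_threshold,
            chunk_size = as.integer(chunk_size),
            chunk_overlap = as.integer(chunk_overlap),
            prescan_min = prescan_min, stop_score = stop_score)
  class(p) <- "search_params"
  p
}

empty_hits <- function() {
  data.frame(target = character(), start = integer(), end = integer(),
             strand = character(), frame = character(), qstart = integer(),
             qend = integer(), score = numeric(), query = character(),
             stringsAsFactors = FALSE)
}

# best local alignments of the query against a batch of frame translations
# (one per window/frame/strand); a single vectorized pairwiseAlignment call
# keeps per-call overhead off the critical path for megabase targets.
align_batch <- function(translations, meta, query, smat, params,
                        target_id, query_id) {
  keep <- nzchar(translations)
  translations <- translations[keep]
  meta <- meta[keep, , drop = FALSE]
  if (!length(translations)) return(NULL)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(translations), Biostrings::AAString(query),
    type = "local", substitutionMatrix = smat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  sc <- Biostrings::score(pa)
  pass <- which(sc >= params$min_score)
  if (!length(pass)) return(NULL)
  qs <- Biostrings::start(Biostrings::subject(pa))[pass] - 1L   # 0-based aa
  qe <- Biostrings::end(Biostrings::subject(pa))[pass]
  ss <- Biostrings::start(Biostrings::pattern(pa))[pass] - 1L
  se <- Biostrings::end(Biostrings::pattern(pa))[pass]
  m <- meta[pass, , drop = FALSE]
  start_s <- m$frame + 3L * (m$aa0 + ss)   # on the hit's own strand
  end_s <- m$frame + 3L * (m$aa0 + se)
  plus <- m$strand == "+"
  t0 <- ifelse(plus, start_s, m$slen - end_s)
  t1 <- ifelse(plus, end_s, m$slen - start_s)
  data.frame(target = target_id, start = as.integer(t0),
             end = as.integer(t1), strand = m$strand,
             frame = as.character(m$frame), qstart = qs, qend = qe,
             score = sc[pass], query = query_id, stringsAsFactors = FALSE)
}

#' Six-frame translated local search
#'
#' Aligns a protein query against all six frame translations of a
#' nucleotide target (Smith-Waterman via Biostrings).  Stop codons are
#' translated as `*` and score `stop_score` against everything; ambiguity
#' codes translate as `X`.  Long targets are scanned in overlapping
#' windows, each window contributing its best local alignment per frame;
#' duplicated hits from overlapping windows are collapsed.  Coordinates are
#' reported 0-based half-open on the plus strand with a strand flag.
#'
#' @param target nucleotide sequence (character).
#' @param query protein sequence (character).
#' @param params a [search_params()].
#' @param target_id,query_id identifiers carried into the hit table.
#' @return data.frame of translated hits.
#' @export
translated_search <- function(target, query, params = search_params(),
                              target_id = "target", query_id = "query") {
  target <- check_dna(target, "target")
  query <- check_protein(query, "query")
  if (nchar(target) < 3L) stopf("target must be at least 3 nt")
  if (!nchar(query)) stopf("query must be non-empty")
  smat <- search_matrix(params$matrix, params$stop_score)
  n <- nchar(target)
  single <- n <= params$chunk_size
  qlen <- nchar(query)
  translations <- character(0)
  meta <- list()
  target_rc <- revcomp(target)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") target else target_rc
    for (fr in 0:2) {
      aa <- translate_frame(s, fr)
      naa <- nchar(aa)
      if (naa < 1L) next
      if (single) {
        regions <- cbind(0L, naa)
      } else {
        sc <- ungapped_scan(aa, query, smat)
        cand <- which(sc >= params$prescan_min)
        if (!length(cand)) next
        # cluster nearby candidate offsets into disjoint regions, padded
        pad <- 50L
        brk <- c(0L, which(diff(cand) > qlen), length(cand))
        regions <- t(vapply(seq_len(length(brk) - 1L), function(i) {
          lo <- cand[brk[i] + 1L]; hi <- cand[brk[i + 1L]]
          c(max(0L, lo - 1L - pad), min(naa, hi - 1L + qlen + pad))
        }, integer(2)))
      }
      for (r in seq_len(nrow(regions))) {
        a0 <- regions[r, 1]
        translations <- c(translations,
                          substr(aa, a0 + 1L, regions[r, 2]))
        meta[[length(meta) + 1L]] <- data.frame(
          aa0 = a0, strand = strand, frame = fr, slen = nchar(s))
      }
    }
  }
  hits <- if (length(translations))
    align_batch(translations, do.call(rbind, meta), query, smat, params,
                target_id, query_id) else NULL
  hits <- do.call(rbind, c(list(empty_hits()), list(hits)))
  if (nrow(hits) > 1L) {  # collapse duplicates from overlapping windows
    key <- paste(hits$start, hits$end, hits$strand, hits$frame)
    hits <- do.call(rbind, lapply(split(hits, key),
                                  function(h) h[which.max(h$score), ]))
  }
  hits <- hits[order(hits$start, hits$end, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# ungapped score of the full query placed at every offset of a frame
# translation (no gaps, stops via the modified matrix), vectorized over
# offsets; the cheap sensitivity pass behind the megabase search path.
ungapped_scan <- function(aa, query, smat) {
  chars <- strsplit(aa, "")[[1]]
  qchars <- strsplit(query, "")[[1]]
  naa <- length(chars)
  qlen <- length(qchars)
  if (naa < qlen) return(numeric(0))
  alpha <- rownames(smat)
  idx <- match(chars, alpha)
  idx[is.na(idx)] <- match("X", alpha)
  nw <- naa - qlen + 1L
  sc <- numeric(nw)
  for (j in seq_len(qlen)) {
    col <- smat[, qchars[j]]
    sc <- sc + col[idx[seq(j, j + nw - 1L)]]
  }
  sc
}

# merge predicate for two hits: same strand, target gap within tolerance,
# query intervals collinear in query orientation with <= aa_overlap overlap.
hits_mergeable <- function(a, b, merge_gap, aa_overlap = 5L) {
  if (a$strand != b$strand) return(FALSE)
  gap <- interval_gap(a$start, a$end, b$start, b$end)
  if (gap > merge_gap) return(FALSE)
  qov <- min(a$qend, b$qend) - max(a$qstart, b$qstart)
  if (qov > aa_overlap) return(FALSE)
  if (a$strand == "+") (a$start <= b$start) == (a$qstart <= b$qstart)
  else (a$start <= b$start) == (b$qstart <= a$qstart)
}

#' Merge frame-split hits
#'
#' Hits from the same gene in different reading frames are unioned: hits on
#' the same strand whose target intervals overlap or are separated by at
#' most the merge gap tolerance, and whose query intervals are collinear
#' (5'-3' order matching query order, overlap of at most 5 aa), are merged
#' by single-linkage closure.  The merged score is the sum of member
#' scores; frame becomes "mixed" when members disagree.
#'
#' @param hits hit data.frame (one target).
#' @param params a [search_params()].
#' @return merged hit data.frame.
#' @export
merge_frame_hits <- function(hits, params = search_params()) {
  if (!nrow(hits)) return(hits)
  if (length(unique(hits$target)) > 1L)
    stopf("merge_frame_hits expects hits from a single target")
  n <- nrow(hits)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (hits_mergeable(hits[i, ], hits[j, ], params$merge_gap)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- lapply(split(seq_len(n), comp), function(idx) {
    h <- hits[idx, , drop = FALSE]
    data.frame(target = h$target[1], start = min(h$start), end = max(h$end),
               strand = h$strand[1],
               frame = if (length(unique(h$frame)) == 1L) h$frame[1]
                       else "mixed",
               qstart = min(h$qstart), qend = max(h$qend),
               score = sum(h$score), query = h$query[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extend a hit flush to the query
#'
#' Retrieves the nucleotides 5' and/or 3' of the hit which would make the
#' alignment flush with the query ends: 3 x (query start) nt upstream and
#' 3 x (query length - query end) nt downstream in query orientation,
#' clipped to the target bounds.  Never shrinks the interval.
#'
#' @param hit one-row hit data.frame.
#' @param query_length query length in aa.
#' @param target_length target bounds (bp).
#' @return the hit with extended `start`/`end` and a logical `clipped`
#'   column set when the extension ran into a target boundary.
#' @export
flush_extend <- function(hit, query_length, target_length) {
  up <- 3L * hit$qstart
  down <- 3L * (query_length - hit$qend)
  if (hit$strand == "-") { tmp <- up; up <- down; down <- tmp }
  new_start <- hit$start - up
  new_end <- hit$end + down
  clipped <- new_start < 0L || new_end > target_length
  hit$start <- max(0L, new_start)
  hit$end <- min(as.integer(target_length), new_end)
  hit$clipped <- clipped
  hit
}

#' Build a position-specific score matrix from aligned domain exemplars
#'
#' Log2-odds of observed residue frequencies (with pseudocounts) over a
#' uniform background.  Gap-majority columns are dropped.
#'
#' @param alignment named character vector of aligned protein sequences.
#' @param kind domain kind label, e.g. "RVP" or "RVT_1".
#' @param pseudocount added per residue.
#' @return matrix 20 x L of class `erv_pssm` with attributes `kind` and
#'   `consensus`.
#' @export
build_pssm <- function(alignment, kind = "domain", pseudocount = 1) {
  rows <- strsplit(toupper(alignment), "")
  L <- unique(lengths(rows))
  if (length(L) != 1L) stopf("exemplar alignment rows differ in length")
  m <- do.call(rbind, rows)
  keep <- colMeans(m == "-") < 0.5
  m <- m[, keep, drop = FALSE]
  if (ncol(m) < 10L) stopf("profile must have at least 10 columns")
  pssm <- sapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    counts <- table(factor(col[col %in% AA20], levels = AA20))
    freq <- (counts + pseudocount) / (sum(counts) + 20 * pseudocount)
    log2(as.numeric(freq) / (1 / 20))
  })
  rownames(pssm) <- AA20
  structure(pssm, class = "erv_pssm", kind = kind,
            consensus = paste(AA20[apply(pssm, 2, which.max)], collapse = ""))
}

#' Scan a nucleotide target with a protein PSSM in six frames
#'
#' Windows in every frame translation scoring at least the profile
#' threshold (bits) are reported as domain hits; stops, `X` and other
#' non-standard residues contribute zero.  Overlapping windows on the same
#' strand are reduced to local score maxima.
#'
#' @param target nucleotide sequence.
#' @param pssm an [build_pssm()] profile.
#' @param params a [search_params()].
#' @param target_id identifier for the hit table.
#' @return annotation-style data.frame of domain hits with `score` (bits)
#'   and `kind` = the profile kind.
#' @export
profile_scan <- function(target, pssm, params = search_params(),
                         target_id = "target") {
  if (!inherits(pssm, "erv_pssm")) stopf("configuration error: not a PSSM")
  target <- check_dna(target, "target")
  L <- ncol(pssm)
  n <- nchar(target)
  hits <- list()
  for (strand in c("+", "-")) {
    seqs <- if (strand == "+") target else revcomp(target)
    for (fr in 0:2) {
      aa <- strsplit(translate_frame(seqs, fr), "")[[1]]
      if (length(aa) < L) next
      idx <- match(aa, AA20)           # NA for *, X, etc.
      idx[is.na(idx)] <- 21L           # non-standard symbols contribute 0
      pssm_ext <- rbind(pssm, 0)
      # sliding window score: accumulate the column-j contribution of the
      # residue at window offset + j, vectorized over window starts.
      nw <- length(aa) - L + 1L
      wscore <- numeric(nw)
      for (j in seq_len(L))
        wscore <- wscore + pssm_ext[(j - 1L) * 21L + idx[seq(j, j + nw - 1L)]]
      pass <- which(wscore >= params$profile_threshold)
      if (!length(pass)) next
      # keep local maxima among runs of overlapping passing windows
      runs <- split(pass, cumsum(c(1L, diff(pass) > L)))
      for (r in runs) {
        best <- r[which.max(wscore[r])]
        aa0 <- best - 1L
        if (strand == "+") {
          t0 <- fr + 3L * aa0
          t1 <- fr + 3L * (aa0 + L)
        } else {
          t0 <- n - fr - 3L * (aa0 + L)
          t1 <- n - fr - 3L * aa0
        }
        hits[[length(hits) + 1L]] <- data.frame(
          target = target_id, start = t0, end = t1, strand = strand,
          frame = as.character(fr), score = wscore[best],
          kind = attr(pssm, "kind"), source = "profile_scan",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(list(data.frame(target = character(),
                                          start = integer(), end = integer(),
                                          strand = character(),
                                          frame = character(),
                                          score = numeric(),
                                          kind = character(),
                                          source = character(),
                                          stringsAsFactors = FALSE)), hits))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
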