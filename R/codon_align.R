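# Codon-aware multiple alignment: each nucleotide sequence is first
# segmented into codon units by a frame-path dynamic program (1-2 nt slips
# allowed at a penalty, internal stops penalized but kept), the resulting
# translations are aligned progressively (UPGMA guide tree, affine-gap
# profile-profile DP over BLOSUM62 expected scores), and the nucleotides
# are threaded back through the protein alignment as intact codons.
# Frameshift slips appear as "!" (1 nt missing) / "!!" (2 nt missing) in
# the nucleotide rows; removing "-" and "!" from any row reproduces its
# input exactly.

#' Segment a nucleotide sequence into codon units with frameshift slips
#'
#' Dynamic program over consumed prefixes: a step consumes 3 nt (a codon;
#' internal stops cost `stop_penalty`), or 1-2 nt (a slip, cost
#' `fs_penalty`).  Leading and trailing partial codons are free (sequence
#' truncation is not a frameshift).
#'
#' @param nt nucleotide sequence.
#' @param fs_penalty cost of a 1-2 nt slip.
#' @param stop_penalty cost of an internal stop codon.
#' @return data.frame of units: `start` (0-based nt), `len` (1-3),
#'   `kind` ("codon", "fs", "partial"), `aa` (translation; `X` for partial
#'   units, `*` for stops).
#' @keywords internal
frame_segment <- function(nt, fs_penalty = 8, stop_penalty = 10) {
  n <- nchar(nt)
  if (n < 3L) stopf("input error: sequence shorter than one codon")
  chars <- strsplit(nt, "")[[1]]
  codon_at <- function(i) paste(chars[(i - 2L):i], collapse = "")  # ends at i
  NEG <- -1e9
  best <- c(0, rep(NEG, n))       # best[i+1] = score with i nt consumed
  back <- integer(n + 1L)         # step length taken to reach i
  for (i in seq_len(n)) {
    cand <- c(`3` = if (i >= 3L) {
                aa <- GENCODE[codon_at(i)]
                best[i - 2L] - (if (!is.na(aa) && aa == "*")
                                  stop_penalty else 0)
              } else NEG,
              `2` = if (i >= 2L) best[i - 1L] -
                (if (i == 2L) 0 else fs_penalty) else NEG,
              `1` = best[i] - (if (i == 1L) 0 else fs_penalty))
    k <- which.max(cand)
    best[i + 1L] <- cand[k]
    back[i + 1L] <- c(3L, 2L, 1L)[k]
  }
  # free trailing partial unit
  fin <- c(best[n + 1L], best[n], best[n - 1L])
  tail_len <- which.max(fin) - 1L
  i <- n - tail_len
  units <- if (tail_len > 0L)
    list(data.frame(start = i, len = tail_len, kind = "partial",
                    stringsAsFactors = FALSE)) else list()
  while (i > 0L) {
    step <- back[i + 1L]
    kind <- if (step == 3L) "codon" else if (i <= 2L) "partial" else "fs"
    units[[length(units) + 1L]] <- data.frame(start = i - step, len = step,
                                              kind = kind,
                                              stringsAsFactors = FALSE)
    i <- i - step
  }
  units <- do.call(rbind, rev(units))
  units$aa <- vapply(seq_len(nrow(units)), function(u) {
    if (units$len[u] < 3L) return("X")
    cod <- substr(nt, units$start[u] + 1L, units$start[u] + 3L)
    if (grepl("[^ACGT]", cod)) "X" else GENCODE[[cod]]
  }, character(1))
  units
}

#' Segment a sequence into codon units guided by a reference
#'
#' Aligns the row against an intact reference nucleotide sequence and
#' derives codon units from the reference frame: indels that are not a
#' multiple of 3 become slip units.  This catches frameshifts that a
#' stop-driven segmentation cannot see (e.g. a slip near a sequence end
#' whose frame is compensated by the extraction boundary).  Units touching
#' the row ends are truncation ("partial"), not frameshifts.
#'
#' @param nt row nucleotide sequence.
#' @param guide intact reference nucleotide sequence (in frame).
#' @return unit data.frame as in [frame_segment()].
#' @keywords internal
frame_segment_guided <- function(nt, guide) {
  if (nchar(nt) < 3L) stopf("input error: sequence shorter than one codon")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(nt), Biostrings::DNAString(guide),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -2),
    gapOpening = 16, gapExtension = 4)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  # guide codon index for every alignment column (insertions inherit the
  # current codon; columns before the guide start get index -1)
  gc <- cumsum(s != "-") - 1L
  codon_idx <- ifelse(gc < 0L, -1L, gc %/% 3L)
  rowcols <- which(p != "-")
  row_codon <- codon_idx[rowcols]
  units <- list()
  pos <- 0L
  for (grp in split(seq_along(rowcols), factor(row_codon,
                                               levels = unique(row_codon)))) {
    n <- length(grp)
    while (n > 0L) {
      take <- if (n >= 3L) 3L else n
      units[[length(units) + 1L]] <- data.frame(
        start = pos, len = take,
        kind = if (take == 3L) "codon" else "fs",
        stringsAsFactors = FALSE)
      pos <- pos + take
      n <- n - take
    }
  }
  units <- do.call(rbind, units)
  # an in-frame deletion straddling a codon boundary can split into two
  # short units summing to 3; re-fuse them into one intact codon
  i <- 1L
  while (i < nrow(units)) {
    if (units$len[i] < 3L && units$len[i + 1L] < 3L &&
        units$len[i] + units$len[i + 1L] == 3L) {
      units$len[i] <- 3L
      units$kind[i] <- "codon"
      units <- units[-(i + 1L), , drop = FALSE]
    } else i <- i + 1L
  }
  short <- units$len < 3L
  at_edge <- units$start == 0L | (units$start + units$len) == nchar(nt)
  units$kind[short & at_edge] <- "partial"
  units$aa <- vapply(seq_len(nrow(units)), function(u) {
    if (units$len[u] < 3L) return("X")
    cod <- substr(nt, units$start[u] + 1L, units$start[u] + 3L)
    if (grepl("[^ACGT]", cod)) "X" else GENCODE[[cod]]
  }, character(1))
  units
}

# translation char matrix helpers ------------------------------------------

b62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

profile_freqs <- function(chars_mat, alphabet) {
  # column frequency matrix over the substitution alphabet, gaps excluded
  apply(chars_mat, 2, function(col) {
    col <- col[col != "-"]
    f <- table(factor(col, levels = alphabet))
    tot <- sum(f)
    if (tot == 0) rep(0, length(alphabet)) else as.numeric(f) / tot
  })
}

# affine-gap global profile-profile alignment; returns list(a_cols, b_cols)
# of expanded column indices (NA = gap column).
align_profiles <- function(charsA, charsB, gap_open = 11, gap_extend = 1) {
  alpha <- rownames(b62())
  FA <- profile_freqs(charsA, alpha)
  FB <- profile_freqs(charsB, alpha)
  S <- t(FA) %*% b62() %*% FB           # expected score per column pair
  la <- ncol(charsA); lb <- ncol(charsB)
  NEG <- -1e9
  M <- matrix(NEG, la + 1L, lb + 1L)    # match state
  X <- matrix(NEG, la + 1L, lb + 1L)    # gap in B (A column unmatched)
  Y <- matrix(NEG, la + 1L, lb + 1L)    # gap in A
  M[1, 1] <- 0
  for (i in seq_len(la) + 1L)
    X[i, 1] <- -gap_open - gap_extend * (i - 1L)
  for (j in seq_len(lb) + 1L)
    Y[1, j] <- -gap_open - gap_extend * (j - 1L)
  for (i in seq_len(la) + 1L) {
    for (j in seq_len(lb) + 1L) {
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + S[i - 1L, j - 1L]
      X[i, j] <- max(M[i - 1L, j] - gap_open - gap_extend,
                     X[i - 1L, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1L] - gap_open - gap_extend,
                     Y[i, j - 1L] - gap_extend)
    }
  }
  # traceback
  i <- la + 1L; j <- lb + 1L
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  a_cols <- integer(0); b_cols <- integer(0)
  while (i > 1L || j > 1L) {
    if (i == 1L) state <- 3L else if (j == 1L) state <- 2L
    if (state == 1L) {
      a_cols <- c(i - 1L, a_cols); b_cols <- c(j - 1L, b_cols)
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      i <- i - 1L; j <- j - 1L
      state <- which.max(prev + c(0, 0, 0))
      if (i == 1L && j == 1L) break
    } else if (state == 2L) {
      a_cols <- c(i - 1L, a_cols); b_cols <- c(NA_integer_, b_cols)
      state <- if (isTRUE(all.equal(
        X[i, j], M[i - 1L, j] - gap_open - gap_extend))) 1L else 2L
      i <- i - 1L
    } else {
      a_cols <- c(NA_integer_, a_cols); b_cols <- c(j - 1L, b_cols)
      state <- if (isTRUE(all.equal(
        Y[i, j], M[i, j - 1L] - gap_open - gap_extend))) 1L else 3L
      j <- j - 1L
    }
    if (i == 1L && j == 1L) break
  }
  list(a_cols = a_cols, b_cols = b_cols)
}

# k-mer distance between protein strings, for the guide tree only
kmer_distance <- function(strings, k = 3L) {
  km <- lapply(strings, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  })
  n <- length(strings)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    shared <- sum(pmin(table(km[[i]])[names(table(km[[j]]))],
                       table(km[[j]])), na.rm = TRUE)
    denom <- max(1L, min(length(km[[i]]), length(km[[j]])))
    d[i, j] <- d[j, i] <- 1 - shared / denom
  }
  d
}

#' Codon-aware multiple alignment
#'
#' @param sequences named character vector of nucleotide sequences (>= 2).
#' @param fs_penalty,stop_penalty frame-segmentation penalties.
#' @param gap_open,gap_extend affine gap penalties for the protein
#'   alignment.
#' @param guide optional intact in-frame reference nucleotide sequence (or
#'   the name of one of `sequences`): rows are then segmented against it
#'   ([frame_segment_guided()]), which also detects frame slips that leave
#'   no stop-codon trace; without a guide, segmentation is the stop-driven
#'   dynamic program.
#' @return object of class `codon_alignment`: `ids`; `nt` (aligned
#'   nucleotide rows with `-` gaps and `!` frameshift padding); `aa`
#'   (aligned translations); `events` (per-row stop/frameshift table with
#'   source coordinates and alignment columns); `map` (rows x columns
#'   matrix of 0-based source nt offsets, NA at gaps).
#' @export
align_codon_aware <- function(sequences, fs_penalty = 8, stop_penalty = 10,
                              gap_open = 11, gap_extend = 1, guide = NULL) {
  if (length(sequences) < 2L) stopf("need at least 2 sequences")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  sequences <- vapply(sequences, check_dna, character(1))
  if (!is.null(guide) && guide %in% names(sequences))
    guide <- sequences[[guide]]
  segs <- if (is.null(guide))
    lapply(sequences, frame_segment, fs_penalty = fs_penalty,
           stop_penalty = stop_penalty)
  else lapply(sequences, frame_segment_guided, guide = guide)
  prots <- vapply(segs, function(u) paste(u$aa, collapse = ""), character(1))

  n <- length(sequences)
  ord_ids <- order(names(sequences))    # lexicographic tie-break
  d <- kmer_distance(prots)[ord_ids, ord_ids, drop = FALSE]
  dimnames(d) <- list(names(sequences)[ord_ids], names(sequences)[ord_ids])
  states <- lapply(ord_ids, function(i) {
    u <- segs[[i]]
    list(rows = i,
         chars = matrix(u$aa, nrow = 1L),
         idx = matrix(seq_len(nrow(u)), nrow = 1L))
  })
  if (n == 2L) {
    merge_order <- matrix(c(-1L, -2L), 1L)
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = "average")  # UPGMA
    merge_order <- hc$merge
  }
  merged <- vector("list", nrow(merge_order))
  get_state <- function(ref) if (ref < 0) states[[-ref]] else merged[[ref]]
  for (m in seq_len(nrow(merge_order))) {
    A <- get_state(merge_order[m, 1]); B <- get_state(merge_order[m, 2])
    tr <- align_profiles(A$chars, B$chars, gap_open, gap_extend)
    ncols <- length(tr$a_cols)
    expand <- function(state, cols) {
      ch <- matrix("-", nrow(state$chars), ncols)
      ix <- matrix(NA_integer_, nrow(state$chars), ncols)
      ok <- !is.na(cols)
      ch[, ok] <- state$chars[, cols[ok], drop = FALSE]
      ix[, ok] <- state$idx[, cols[ok], drop = FALSE]
      list(chars = ch, idx = ix)
    }
    eA <- expand(A, tr$a_cols); eB <- expand(B, tr$b_cols)
    merged[[m]] <- list(rows = c(A$rows, B$rows),
                        chars = rbind(eA$chars, eB$chars),
                        idx = rbind(eA$idx, eB$idx))
  }
  fin <- merged[[length(merged)]]
  row_of <- match(seq_len(n), fin$rows)

  ncols <- ncol(fin$chars)
  nt_rows <- character(n); aa_rows <- character(n)
  map <- matrix(NA_integer_, n, ncols,
                dimnames = list(names(sequences), NULL))
  events <- list()
  for (i in seq_len(n)) {
    u <- segs[[i]]
    idx <- fin$idx[row_of[i], ]
    aa_rows[i] <- paste(fin$chars[row_of[i], ], collapse = "")
    cods <- vapply(seq_len(ncols), function(j) {
      if (is.na(idx[j])) return("---")
      uu <- u[idx[j], ]
      raw <- substr(sequences[[i]], uu$start + 1L, uu$start + uu$len)
      paste0(raw, strrep("!", 3L - uu$len))
    }, character(1))
    nt_rows[i] <- paste(cods, collapse = "")
    map[i, !is.na(idx)] <- u$start[idx[!is.na(idx)]]
    ev_fs <- which(u$kind == "fs")
    ev_st <- which(u$aa == "*")
    mkev <- function(un, type) data.frame(
      id = names(sequences)[i], type = type, source_pos = u$start[un],
      column = match(un, idx), stringsAsFactors = FALSE)
    if (length(ev_fs)) events[[length(events) + 1L]] <- mkev(ev_fs, "frameshift")
    if (length(ev_st)) events[[length(events) + 1L]] <- mkev(ev_st, "stop")
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(id = character(), type = character(), source_pos = integer(),
               column = integer(), stringsAsFactors = FALSE)
  structure(list(ids = names(sequences),
                 nt = stats::setNames(nt_rows, names(sequences)),
                 aa = stats::setNames(aa_rows, names(sequences)),
                 events = events, map = map),
            class = "codon_alignment")
}

#' Recover an input sequence from its aligned row
#' @param ca a `codon_alignment`.
#' @param id row id.
#' @return the ungapped original nucleotide sequence.
#' @export
ungap_row <- function(ca, id) {
  gsub("[-!]", "", ca$nt[[id]])
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d rows x %d aa columns, %d events\n",
              length(x$ids), nchar(x$aa[[1]]) , nrow(x$events)))
  invisible(x)
}

#' Pairwise protein distances from aligned translations
#'
#' Kimura-style correction of the p-distance over shared non-gap columns:
#' `d = -ln(1 - p - 0.2 p^2)`.  Pairs with no shared columns (or p beyond
#' the formula's domain) are NA and listed in attribute `undefined_pairs`.
#'
#' @param aa_rows named character vector of aligned protein rows.
#' @return symmetric distance matrix with zero diagonal.
#' @export
pairwise_protein_distance <- function(aa_rows) {
  m <- do.call(rbind, strsplit(aa_rows, ""))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(aa_rows), names(aa_rows)))
  undef <- character(0)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok)) {
      d[i, j] <- d[j, i] <- NA_real_
      undef <- c(undef, paste(names(aa_rows)[c(i, j)], collapse = ":"))
      next
    }
    p <- mean(m[i, ok] != m[j, ok])
    arg <- 1 - p - 0.2 * p^2
    if (arg <= 0) {
      d[i, j] <- d[j, i] <- NA_real_
      undef <- c(undef, paste(names(aa_rows)[c(i, j)], collapse = ":"))
    } else {
      d[i, j] <- d[j, i] <- -log(arg)
    }
  }
  attr(d, "undefined_pairs") <- undef
  d
}
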