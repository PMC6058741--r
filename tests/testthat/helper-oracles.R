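# Independent oracles used by the property and acceptance tests.  These
# deliberately re-derive results by brute force (plain dynamic programs,
# exhaustive enumeration) and never call the code paths they check.

AA20_T <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
random_protein <- function(n) paste(sample(AA20_T, n, replace = TRUE),
                                    collapse = "")

# mutate a protein string at a given divergence (replacement model)
mutate_protein <- function(aa, divergence) {
  ch <- strsplit(aa, "")[[1]]
  idx <- sample(length(ch), round(divergence * length(ch)))
  ch[idx] <- sample(AA20_T, length(idx), replace = TRUE)
  paste(ch, collapse = "")
}

# plain-R affine-gap local (Smith-Waterman) alignment score.
# Convention: a gap of length L costs gap_open + L * gap_extend.
sw_score_oracle <- function(pattern, subject, smat, gap_open = 11,
                            gap_extend = 1) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  np <- length(p); ns <- length(s)
  if (!np || !ns) return(0)
  NEG <- -1e9
  H <- matrix(0, np + 1L, ns + 1L)
  E <- matrix(NEG, np + 1L, ns + 1L)  # gap in pattern (move along subject)
  F <- matrix(NEG, np + 1L, ns + 1L)  # gap in subject
  best <- 0
  for (i in seq_len(np) + 1L) {
    for (j in seq_len(ns) + 1L) {
      E[i, j] <- max(H[i, j - 1L] - gap_open - gap_extend,
                     E[i, j - 1L] - gap_extend)
      F[i, j] <- max(H[i - 1L, j] - gap_open - gap_extend,
                     F[i - 1L, j] - gap_extend)
      sc <- smat[p[i - 1L], s[j - 1L]]
      H[i, j] <- max(0, H[i - 1L, j - 1L] + sc, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# translation table used by the oracles (independent of the package helper)
oracle_translate <- function(nt, frame) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(nt)
  starts <- seq(frame + 1L, n - 2L, by = 3L)
  if (!length(starts)) return("")
  cods <- substring(nt, starts, starts + 2L)
  aa <- ifelse(grepl("[^ACGT]", cods), "X",
               unname(code[cods]))
  paste(aa, collapse = "")
}

# exhaustive single-linkage closure over an arbitrary pairwise predicate:
# repeated boolean matrix squaring until fixpoint, then component labels.
closure_oracle <- function(n, pred) {
  if (n == 0) return(integer(0))
  A <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && isTRUE(pred(i, j))) A[i, j] <- A[j, i] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[A[i, ] > 0] <- cur
    }
  }
  comp
}

# canonical form of a partition for comparisons
canon_partition <- function(labels) match(labels, unique(labels))

# exhaustive repeat-pair oracle: for every pair of positions sharing a
# k-mer at an allowed separation, scan all windows around it and report
# whether any window passes the length/identity thresholds.
repeat_pair_oracle <- function(seqchars, k, ltr_range, spacing_range,
                               min_identity) {
  n <- length(seqchars)
  base <- match(seqchars, c("A", "C", "G", "T")) - 1L
  np <- n - k + 1L
  code <- numeric(np)
  for (j in seq_len(k)) code <- code * 4 + base[seq(j, j + np - 1L)]
  ord <- order(code, seq_len(np))
  codes <- code[ord]; pos <- ord
  found <- list()
  seen <- new.env(hash = TRUE)   # one evaluation per (diagonal, vicinity)
  i <- 1L
  while (i <= np) {
    j <- i
    while (j < np && codes[j + 1L] == codes[i]) j <- j + 1L
    if (j > i) {
      ps <- pos[i:j]
      for (a in seq_len(length(ps) - 1L)) for (b in seq(a + 1L, length(ps))) {
        d <- abs(ps[b] - ps[a])
        if (d < spacing_range[1] || d > spacing_range[2]) next
        p1 <- min(ps[a], ps[b])
        key <- as.character(d)
        prior <- get0(key, envir = seen, ifnotfound = integer(0))
        if (any(abs(prior - p1) <= ltr_range[2])) next
        assign(key, c(prior, p1), envir = seen)
        lo_lim <- max(1L, p1 - ltr_range[2])
        hi_lim <- min(n - d, p1 + ltr_range[2])
        idx <- seq(lo_lim, hi_lim)
        mv <- seqchars[idx] == seqchars[idx + d]
        cs <- cumsum(c(0L, mv))
        best <- NULL
        for (len in seq(ltr_range[1], min(ltr_range[2], length(mv)))) {
          wins <- seq_len(length(mv) - len + 1L)
          ident <- (cs[wins + len] - cs[wins]) / len
          ok <- which(ident >= min_identity)
          # window must contain the seed
          seed_rel <- p1 - lo_lim + 1L
          ok <- ok[ok <= seed_rel & ok + len - 1L >= seed_rel + k - 1L]
          if (length(ok)) {
            w <- ok[which.max(ident[ok])]
            cand <- c(start = lo_lim + w - 2L, len = len, d = d,
                      ident = max(ident[ok]))
            if (is.null(best) || cand["ident"] > best["ident"] ||
                (cand["ident"] == best["ident"] && len > best["len"]))
              best <- cand
          }
        }
        if (!is.null(best)) found[[length(found) + 1L]] <- best
      }
    }
    i <- j + 1L
  }
  if (!length(found)) return(NULL)
  do.call(rbind, found)
}

# full-enumeration two-sided rank-sum p-value (independent of the package
# implementation: iterates over combinations via a different construction)
enum_ranksum_oracle <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  idx <- utils::combn(seq_along(pooled), na)
  stats <- apply(idx, 2, function(ix) sum(r[ix]))
  obs <- sum(r[seq_len(na)])
  lo <- sum(stats <= obs + 1e-9) / length(stats)
  hi <- sum(stats >= obs - 1e-9) / length(stats)
  min(1, 2 * min(lo, hi))
}

enum_signedrank_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  stats <- vapply(seq_len(2^n) - 1L, function(mask) {
    bits <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    sum(r[bits])
  }, numeric(1))
  lo <- mean(stats <= obs + 1e-9)
  hi <- mean(stats >= obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# small shared fixtures -----------------------------------------------------

small_refs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_reference_set(rng_seed = 7L)
    cache
  }
})

ref_protein_alignment <- function(refs = small_refs()) {
  vapply(refs$sequences, function(s)
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "X")),
    character(1))
}
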