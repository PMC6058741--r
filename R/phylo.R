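# Reference phylogeny and evolutionary placement.  The reference tree is
# built by neighbor joining on corrected protein distances; queries are
# classified by attaching them to every edge with a pendant branch,
# scoring attachments under a fixed single-rate amino-acid model
# (F81-style: exchangeabilities uniform, stationary frequencies estimated
# from the reference alignment), and normalizing per-edge likelihoods into
# placement weights.

#' Build a labeled reference tree by neighbor joining
#'
#' @param ref_alignment named character vector of aligned reference
#'   proteins (>= 4 rows).
#' @param labels data.frame with columns `id`, `clade` (defaults to leaf
#'   names as their own clades).
#' @param supergroups optional named vector mapping clade -> supergroup.
#' @return object of class `reference_tree`: `tree` (phylo, negative branch
#'   lengths clamped to 0), `clades`, `supergroups`, `alignment`.
#' @export
build_reference_tree <- function(ref_alignment, labels = NULL,
                                 supergroups = NULL) {
  if (length(ref_alignment) < 4L) stopf("need at least 4 references")
  d <- pairwise_protein_distance(ref_alignment)
  undef <- attr(d, "undefined_pairs")
  if (length(undef))
    stopf("undefined distances for pairs: %s", paste(undef, collapse = ", "))
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  if (is.null(labels))
    labels <- data.frame(id = names(ref_alignment),
                         clade = names(ref_alignment),
                         stringsAsFactors = FALSE)
  clades <- stats::setNames(labels$clade, labels$id)
  if (!all(tree$tip.label %in% names(clades)))
    stopf("configuration error: unlabeled leaves: %s",
          paste(setdiff(tree$tip.label, names(clades)), collapse = ", "))
  structure(list(tree = tree, clades = clades[tree$tip.label],
                 supergroups = supergroups, alignment = ref_alignment),
            class = "reference_tree")
}

# --- fixed amino-acid substitution model (single rate, F81-style) ---------

aa_model <- function(ref_alignment, pseudocount = 1,
                     freq = c("empirical", "uniform")) {
  freq <- match.arg(freq)
  if (freq == "uniform") {
    pi <- rep(1 / 20, 20)
  } else {
    chars <- unlist(strsplit(ref_alignment, ""))
    counts <- table(factor(chars[chars %in% AA20], levels = AA20))
    pi <- (as.numeric(counts) + pseudocount) /
      (sum(counts) + 20 * pseudocount)
  }
  list(pi = pi, beta = 1 / (1 - sum(pi^2)))
}

aa_pmat <- function(model, t) {
  e <- exp(-model$beta * t)
  P <- matrix((1 - e) * rep(model$pi, each = 20), 20, 20)
  diag(P) <- diag(P) + e
  P
}

# tip conditional-likelihood matrix (20 x L); unknown residues -> all ones
encode_tip <- function(seq_chars) {
  L <- length(seq_chars)
  m <- matrix(1, 20, L)
  idx <- match(seq_chars, AA20)
  known <- which(!is.na(idx))
  if (length(known)) {
    m[, known] <- 0
    m[cbind(idx[known], known)] <- 1
  }
  m
}

# scaled conditional: list(mat = 20 x L, logs = per-column log scale)
scale_cond <- function(mat, logs) {
  mx <- apply(mat, 2, max)
  mx[mx == 0] <- 1
  list(mat = sweep(mat, 2, mx, "/"), logs = logs + log(mx))
}

#' Precompute per-edge placement contexts
#'
#' Two-pass (post-order / pre-order) conditional likelihoods on the
#' reference tree, combined into one context per edge: the likelihood
#' contribution of both sides of the edge as seen from an attachment point
#' at the edge midpoint.
#'
#' @param rt a [build_reference_tree()] result.
#' @param ref_alignment aligned reference proteins (defaults to the
#'   alignment stored in `rt`).
#' @param freq stationary frequencies: "empirical" (estimated from the
#'   reference alignment, the default) or "uniform" (Poisson-like; makes
#'   per-site mismatch costs residue-independent).
#' @return list of class `placement_engine`.
#' @export
placement_engine <- function(rt, ref_alignment = rt$alignment,
                             freq = c("empirical", "uniform")) {
  tree <- rt$tree
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  rows <- strsplit(ref_alignment[tree$tip.label], "")
  L <- length(rows[[1]])
  model <- aa_model(ref_alignment, freq = match.arg(freq))
  children <- vector("list", nnode)
  parent <- integer(nnode)
  elen <- numeric(nnode)
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    children[[u]] <- c(children[[u]], v)
    parent[v] <- u
    elen[v] <- tree$edge.length[e]
  }
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")$edge  # descendants first
  # post-order down conditionals D and up-going messages
  D <- vector("list", nnode)
  msg_up <- vector("list", nnode)   # P(t_v) %*% D_v, seen at parent of v
  finalize <- function(v) {
    if (is.null(D[[v]]))
      D[[v]] <<- if (v <= ntip)
        list(mat = encode_tip(rows[[v]]), logs = numeric(L))
      else list(mat = matrix(1, 20, L), logs = numeric(L))
    invisible(NULL)
  }
  for (e in seq_len(nrow(po))) {
    u <- po[e, 1]; v <- po[e, 2]
    finalize(v); finalize(u)
    if (v > ntip) D[[v]] <- scale_cond(D[[v]]$mat, D[[v]]$logs)
    P <- aa_pmat(model, elen[v])
    msg_up[[v]] <- list(mat = P %*% D[[v]]$mat, logs = D[[v]]$logs)
    D[[u]] <- list(mat = D[[u]]$mat * msg_up[[v]]$mat,
                   logs = D[[u]]$logs + msg_up[[v]]$logs)
  }
  # pre-order outside conditionals U_v (at parent of v, excluding subtree v)
  U <- vector("list", nnode)
  for (e in rev(seq_len(nrow(po)))) {
    u <- po[e, 1]; v <- po[e, 2]
    mat <- matrix(1, 20, L); logs <- numeric(L)
    if (u != root) {
      P <- aa_pmat(model, elen[u])
      mat <- mat * (P %*% U[[u]]$mat)
      logs <- logs + U[[u]]$logs
    }
    for (w in setdiff(children[[u]], v)) {
      mat <- mat * msg_up[[w]]$mat
      logs <- logs + msg_up[[w]]$logs
    }
    U[[v]] <- scale_cond(mat, logs)
  }
  # per-edge context at the edge midpoint
  edges <- setdiff(seq_len(nnode), root)
  ctx <- vector("list", nnode)
  for (v in edges) {
    Ph <- aa_pmat(model, elen[v] / 2)
    A <- Ph %*% D[[v]]$mat
    B <- Ph %*% U[[v]]$mat
    sc <- scale_cond(A * B, D[[v]]$logs + U[[v]]$logs)
    ctx[[v]] <- sc
  }
  # leaf sets on the child side of each edge
  tipsets <- as.list(seq_len(nnode))
  tipsets[seq(ntip + 1L, nnode)] <- list(integer(0))
  for (e in seq_len(nrow(po)))
    tipsets[[po[e, 1]]] <- c(tipsets[[po[e, 1]]], tipsets[[po[e, 2]]])
  structure(list(model = model, ctx = ctx, edges = edges, L = L,
                 tipsets = tipsets, ntip = ntip,
                 tip_labels = tree$tip.label, rt = rt),
            class = "placement_engine")
}

# align a query protein to frozen reference columns; returns the query row
# expanded to the reference column space ("-" where unmatched).
project_query <- function(ref_alignment, query, gap_open = 11,
                          gap_extend = 1) {
  alpha <- rownames(b62())
  charsR <- do.call(rbind, strsplit(ref_alignment, ""))
  FR <- profile_freqs(charsR, alpha)
  q <- strsplit(toupper(query), "")[[1]]
  qi <- match(q, alpha)
  S <- t(FR) %*% b62()                  # L x alphabet
  L <- ncol(charsR); m <- length(q)
  NEG <- -1e9
  M <- matrix(NEG, L + 1L, m + 1L); Xg <- M; Yg <- M
  M[1, 1] <- 0
  Xg[seq_len(L) + 1L, 1] <- -gap_open - gap_extend * seq_len(L)
  Yg[1, seq_len(m) + 1L] <- -gap_open - gap_extend * seq_len(m)
  for (i in seq_len(L) + 1L) for (j in seq_len(m) + 1L) {
    s <- if (is.na(qi[j - 1L])) 0 else S[i - 1L, qi[j - 1L]]
    M[i, j] <- max(M[i - 1L, j - 1L], Xg[i - 1L, j - 1L],
                   Yg[i - 1L, j - 1L]) + s
    Xg[i, j] <- max(M[i - 1L, j] - gap_open - gap_extend,
                    Xg[i - 1L, j] - gap_extend)
    Yg[i, j] <- max(M[i, j - 1L] - gap_open - gap_extend,
                    Yg[i, j - 1L] - gap_extend)
  }
  out <- rep("-", L)
  i <- L + 1L; j <- m + 1L
  state <- which.max(c(M[i, j], Xg[i, j], Yg[i, j]))
  while (i > 1L || j > 1L) {
    if (i == 1L) state <- 3L else if (j == 1L) state <- 2L
    if (state == 1L) {
      out[i - 1L] <- q[j - 1L]
      prev <- c(M[i - 1L, j - 1L], Xg[i - 1L, j - 1L], Yg[i - 1L, j - 1L])
      i <- i - 1L; j <- j - 1L
      state <- which.max(prev)
    } else if (state == 2L) {
      state <- if (isTRUE(all.equal(
        Xg[i, j], M[i - 1L, j] - gap_open - gap_extend))) 1L else 2L
      i <- i - 1L
    } else {
      state <- if (isTRUE(all.equal(
        Yg[i, j], M[i, j - 1L] - gap_open - gap_extend))) 1L else 3L
      j <- j - 1L
    }
  }
  paste(out, collapse = "")
}

#' Place a query on every edge of the reference tree
#'
#' The query is profile-aligned to the frozen reference columns, attached
#' to each edge midpoint by a pendant branch whose length is optimized by
#' line search over a log grid, and scored by pruning likelihood.  Per-edge
#' weights are the normalized likelihoods (a likelihood-weight-ratio
#' analog).
#'
#' @param rt a [build_reference_tree()] result.
#' @param query protein sequence (aligned to the reference columns or raw).
#' @param engine optional precomputed [placement_engine()] for batch use.
#' @param query_id identifier.
#' @param min_overlap minimum fraction of reference columns the query must
#'   cover; below it the verdict is UNPLACED ("insufficient overlap").
#' @param pendant_grid pendant branch-length grid.  The upper end (5.0)
#'   lets the pendant saturate to the stationary distribution so that a
#'   sequence unrelated to every reference scores near-equally on all
#'   edges and is rejected by the weight threshold, instead of placing
#'   confidently on an arbitrary edge.
#' @return object of class `erv_placement`: per-edge table (`edge` = child
#'   node id, `loglik`, `weight`), `best_edge`, `best_weight`, `query_row`.
#' @export
place_query <- function(rt, query, engine = NULL, query_id = "query",
                        min_overlap = 0.3,
                        pendant_grid = exp(seq(log(1e-4), log(5),
                                               length.out = 10))) {
  if (is.null(engine)) engine <- placement_engine(rt)
  q <- toupper(query)
  row <- if (nchar(q) == engine$L && grepl("-", q, fixed = TRUE)) q
         else if (nchar(q) == engine$L) q
         else project_query(rt$alignment, q)
  qc <- strsplit(row, "")[[1]]
  overlap <- mean(qc != "-")
  if (overlap < min_overlap) {
    out <- list(query = query_id, table = NULL, best_edge = NA_integer_,
                best_weight = NA_real_, verdict = "UNPLACED",
                reason = "insufficient overlap", query_row = row)
    class(out) <- "erv_placement"
    return(out)
  }
  Q <- encode_tip(qc)
  model <- engine$model
  logpi <- log(model$pi)
  lls <- vapply(engine$edges, function(v) {
    ctx <- engine$ctx[[v]]
    max(vapply(pendant_grid, function(tp) {
      C <- aa_pmat(model, tp) %*% Q
      colvals <- colSums(model$pi * ctx$mat * C)
      sum(log(colvals) + ctx$logs)
    }, numeric(1)))
  }, numeric(1))
  w <- exp(lls - max(lls))
  w <- w / sum(w)
  best <- which.max(lls)                # first max: deterministic tie-break
  out <- list(query = query_id,
              table = data.frame(edge = engine$edges, loglik = lls,
                                 weight = w),
              best_edge = engine$edges[best], best_weight = w[best],
              verdict = NA_character_, reason = NA_character_,
              query_row = row, engine_tipsets = engine$tipsets,
              ntip = engine$ntip, tip_labels = engine$tip_labels)
  class(out) <- "erv_placement"
  out
}

#' Classify a placement into a clade verdict
#'
#' UNPLACED when the best weight is below the threshold (published rule:
#' 0.90); otherwise the clade label when one side of the best edge contains
#' leaves of a single clade (pendant edges included); INTERNAL when the
#' edge lies on the path between clades.
#'
#' @param placement an [place_query()] result.
#' @param rt the [build_reference_tree()] used.
#' @param threshold placement probability threshold.
#' @return character verdict.
#' @export
classify_placement <- function(placement, rt, threshold = 0.90) {
  if (identical(placement$verdict, "UNPLACED")) return("UNPLACED")
  if (placement$best_weight < threshold) return("UNPLACED")
  v <- placement$best_edge
  tipset <- placement$engine_tipsets[[v]]
  labels <- rt$clades[placement$tip_labels]
  side1 <- labels[tipset]
  side2 <- labels[-tipset]
  if (length(unique(side1)) == 1L) return(unname(side1[1]))
  if (length(unique(side2)) == 1L) return(unname(side2[1]))
  "INTERNAL"
}

#' Reconcile member verdicts into a locus verdict
#'
#' @param verdicts character vector of member verdicts.
#' @return list with `verdict`, `conflict` flag, and `dissent` (members
#'   disagreeing with the majority, by index).
#' @export
reconcile_locus <- function(verdicts) {
  if (!length(verdicts)) stopf("need at least one member verdict")
  eff <- verdicts[!verdicts %in% c("UNPLACED")]
  if (!length(eff))
    return(list(verdict = "UNPLACED", conflict = FALSE, dissent = integer(0)))
  tab <- sort(table(eff), decreasing = TRUE)
  if (length(tab) == 1L)
    return(list(verdict = names(tab)[1], conflict = FALSE,
                dissent = integer(0)))
  majority <- names(tab)[1]
  list(verdict = "conflict", conflict = TRUE, majority = majority,
       dissent = which(verdicts != majority & verdicts != "UNPLACED"))
}
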