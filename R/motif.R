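# Protease active-site motif extraction and activity triage.  The B1
# active-site loop (canonical DTGAD) and the C2 helix (canonical GRDLL)
# are located by anchoring the consensus of intact references in the codon
# alignment; per-sequence motifs are classified into three activity tiers
# by a data-driven residue rule set.

#' Default activity rule set
#'
#' Encodes the residue tolerances of retropepsin active sites: the
#' catalytic aspartate (B1 position 1) is strict; the dimer-interface
#' threonine admits serine; the flexible glycine admits small or charged
#' substitutions as a deviation; B1 position 4 admits the residues observed
#' in active proteases of other exogenous retroviruses; the closing
#' aspartate admits asparagine and glutamate freely (its character is not
#' critical).  C2 requires the glycine, a large polar residue at position
#' 2, an acidic/His position 3, and the two leucines (Ile tolerated at
#' position 4).  A motif is demoted to inactive when any residue falls
#' outside its allowed set, when B1 carries two deviations, or when B1 and
#' C2 both deviate.
#'
#' @return list of class `activity_rules`.
#' @export
default_activity_rules <- function() {
  rules <- list(
    b1_allowed = list(c("D"),
                      c("T", "S"),
                      c("G", "A", "S", "C", "N", "T", "V", "D", "E", "K",
                        "R", "H"),
                      c("A", "V", "S", "E", "T", "M", "I", "G", "D"),
                      c("D", "N", "E")),
    # positions whose non-canonical (but allowed) residues count as a
    # deviation; B1 position 5 variants are tolerated without deviation
    b1_canonical = list(c("D"), c("T"), c("G"), c("A", "V"),
                        c("D", "N", "E")),
    c2_allowed = list(c("G"), c("R", "K", "Q"), c("D", "E", "H"),
                      c("L", "I"), c("L")),
    c2_canonical = list(c("G"), c("R"), c("D"), c("L"), c("L")),
    b1_active = c("DTGAD", "DTGVD"),
    c2_active = "GRDLL",
    max_b1_deviations = 1L,
    cross_motif_demotion = TRUE)
  class(rules) <- "activity_rules"
  rules
}

#' Locate motif column blocks by consensus anchoring
#'
#' Finds the alignment columns spelling the B1 and C2 consensus of the
#' intact reference rows.
#'
#' @param aa_rows aligned protein rows (named character).
#' @param reference_ids rows used to form the consensus.
#' @param b1_anchor,c2_anchor consensus motifs to anchor.
#' @return list with `b1_cols`, `c2_cols` (alignment column indices).
#' @export
anchor_motif_columns <- function(aa_rows, reference_ids = names(aa_rows),
                                 b1_anchor = "DTGAD", c2_anchor = "GRDLL") {
  m <- do.call(rbind, strsplit(aa_rows[reference_ids], ""))
  cons <- apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return("-")
    names(sort(table(col), decreasing = TRUE))[1]
  })
  nong <- which(cons != "-")
  cons_str <- paste(cons[nong], collapse = "")
  b1_at <- regexpr(b1_anchor, cons_str, fixed = TRUE)
  if (b1_at < 0)
    stopf("configuration error: B1 anchor '%s' not found in reference consensus",
          b1_anchor)
  c2_at <- regexpr(c2_anchor, substr(cons_str, b1_at + 5L, nchar(cons_str)),
                   fixed = TRUE)
  if (c2_at < 0)
    stopf("configuration error: C2 anchor '%s' not found downstream of B1",
          c2_anchor)
  list(b1_cols = nong[seq(b1_at, b1_at + 4L)],
       c2_cols = nong[seq(b1_at + 4L + c2_at, b1_at + 4L + c2_at + 4L)])
}

#' Extract B1/C2 motifs from a codon alignment of mature proteases
#'
#' Gaps inside a motif block are preserved as missing residues (the motif
#' string shrinks); rows all-gap in a block yield an empty motif.
#'
#' @param ca a [align_codon_aware()] result (or list with `aa` rows and
#'   `events`).
#' @param reference_ids intact reference rows used to anchor the blocks.
#' @return data.frame of motif calls: `id`, `b1`, `c2`, `interrupted`
#'   (none/stop/frameshift/both), `activity` (unset NA).
#' @export
extract_motifs <- function(ca, reference_ids) {
  cols <- anchor_motif_columns(ca$aa, reference_ids)
  m <- do.call(rbind, strsplit(ca$aa, ""))
  pull <- function(row, cc) {
    res <- m[row, cc]
    paste(res[res != "-"], collapse = "")
  }
  calls <- data.frame(
    id = ca$ids,
    b1 = vapply(seq_along(ca$ids), pull, character(1), cc = cols$b1_cols),
    c2 = vapply(seq_along(ca$ids), pull, character(1), cc = cols$c2_cols),
    stringsAsFactors = FALSE)
  calls$interrupted <- vapply(ca$ids, function(id)
    flag_interruptions(ca$events[ca$events$id == id, ]), character(1))
  calls$activity <- NA_character_
  attr(calls, "columns") <- cols
  calls
}

#' Interruption status from per-row alignment events
#'
#' @param events data.frame with a `type` column ("stop"/"frameshift").
#' @return "none", "stop", "frameshift" or "both".
#' @export
flag_interruptions <- function(events) {
  has_stop <- any(events$type == "stop")
  has_fs <- any(events$type == "frameshift")
  if (has_stop && has_fs) "both"
  else if (has_stop) "stop"
  else if (has_fs) "frameshift"
  else "none"
}

#' Flag the 38-42 deletion
#'
#' TRUE iff all alignment columns mapping to RVP positions 38-42 (1-based
#' residue positions of the anchor reference row) are gaps in the row.
#'
#' @param ca codon alignment.
#' @param id row to inspect.
#' @param reference_id intact reference row defining RVP coordinates.
#' @param positions residue positions of the deletion block.
#' @return logical flag.
#' @export
flag_38_42_deletion <- function(ca, id, reference_id, positions = 38:42) {
  ref <- strsplit(ca$aa[[reference_id]], "")[[1]]
  cols <- which(ref != "-")[positions]
  if (anyNA(cols)) stopf("reference row shorter than position %d",
                         max(positions))
  row <- strsplit(ca$aa[[id]], "")[[1]]
  all(row[cols] == "-")
}

motif_deviations <- function(motif, allowed, canonical) {
  res <- strsplit(motif, "")[[1]]
  disallowed <- any(vapply(seq_along(res), function(p)
    !(res[p] %in% allowed[[p]]), logical(1)))
  ndev <- sum(vapply(seq_along(res), function(p)
    res[p] %in% allowed[[p]] && !(res[p] %in% canonical[[p]]), logical(1)))
  list(disallowed = disallowed, ndev = ndev)
}

#' Classify predicted protease activity from B1/C2 motifs
#'
#' PREDICTED_ACTIVE for the canonical pairs; PREDICTED_INACTIVE when a
#' motif has the wrong length, carries a residue outside its allowed set,
#' accumulates two deviations in B1, or deviates in both B1 and C2
#' simultaneously; POTENTIALLY_ACTIVE otherwise.
#'
#' @param b1,c2 motif strings.
#' @param rules an [default_activity_rules()] rule set.
#' @return list with `activity` and `trace` (fired rules, in order).
#' @export
classify_activity <- function(b1, c2, rules = default_activity_rules()) {
  b1 <- toupper(b1); c2 <- toupper(c2)
  check_protein(c(b1, c2), "motif")
  trace <- character(0)
  if (b1 %in% rules$b1_active && c2 %in% rules$c2_active)
    return(list(activity = "PREDICTED_ACTIVE", trace = "canonical_pair"))
  if (nchar(b1) != 5L || nchar(c2) != 5L)
    return(list(activity = "PREDICTED_INACTIVE", trace = "motif_length"))
  db1 <- motif_deviations(b1, rules$b1_allowed, rules$b1_canonical)
  dc2 <- motif_deviations(c2, rules$c2_allowed, rules$c2_canonical)
  if (db1$disallowed) trace <- c(trace, "b1_disallowed_residue")
  if (dc2$disallowed) trace <- c(trace, "c2_disallowed_residue")
  if (db1$ndev > rules$max_b1_deviations)
    trace <- c(trace, "b1_multiple_deviations")
  if (rules$cross_motif_demotion && db1$ndev >= 1L && dc2$ndev >= 1L)
    trace <- c(trace, "b1_and_c2_deviate")
  if (length(trace))
    return(list(activity = "PREDICTED_INACTIVE", trace = trace))
  trace <- c(if (db1$ndev) "b1_tolerated_deviation",
             if (dc2$ndev) "c2_tolerated_deviation",
             if (!db1$ndev && !dc2$ndev) "noncanonical_combination")
  list(activity = "POTENTIALLY_ACTIVE", trace = trace)
}

#' Tabulate motif pairs by activity class
#'
#' Interrupted sequences are excluded; counts sum to the number of
#' uninterrupted calls.  Sorted by count descending, then lexicographically.
#'
#' @param calls motif-call data.frame (columns `b1`, `c2`, `interrupted`).
#' @param rules activity rule set.
#' @return data.frame `count`, `b1`, `c2`, `activity`.
#' @export
tabulate_motifs <- function(calls, rules = default_activity_rules()) {
  keep <- calls[calls$interrupted == "none", , drop = FALSE]
  if (!nrow(keep))
    return(data.frame(count = integer(), b1 = character(), c2 = character(),
                      activity = character(), stringsAsFactors = FALSE))
  key <- paste(keep$b1, keep$c2, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    count = as.integer(tab),
    b1 = vapply(parts, `[`, character(1), 1),
    c2 = vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                character(1)),
    stringsAsFactors = FALSE)
  out$activity <- vapply(seq_len(nrow(out)), function(i)
    classify_activity(out$b1[i], out$c2[i], rules)$activity, character(1))
  out <- out[order(-out$count, out$b1, out$c2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Check the classifier against the published motif survey
#'
#' Applies [classify_activity()] to every motif pair of the packaged survey
#' and reports concordance with the published class, with every mismatch
#' in an exception report.
#'
#' @param rules activity rule set.
#' @return list with `concordance` (fraction of pairs matching) and
#'   `exceptions` (data.frame of mismatching pairs).
#' @export
survey_concordance <- function(rules = default_activity_rules()) {
  tab <- ervk_motif_table()
  map <- c(active = "PREDICTED_ACTIVE", potential = "POTENTIALLY_ACTIVE",
           inactive = "PREDICTED_INACTIVE")
  tab$predicted <- vapply(seq_len(nrow(tab)), function(i)
    classify_activity(tab$b1[i], tab$c2[i], rules)$activity, character(1))
  tab$published <- unname(map[tab$class])
  mism <- tab[tab$predicted != tab$published, , drop = FALSE]
  list(concordance = mean(tab$predicted == tab$published),
       exceptions = mism[, c("b1", "c2", "published", "predicted")])
}
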