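# End-to-end orchestration: discover -> classify/motifs -> express, driven
# by a flat configuration, with standard-format outputs (FASTA/GFF3/SAM/
# newick/TSV) and deterministic behavior given the config and seed.

#' Pipeline configuration
#'
#' Houses every stage threshold with its published default where one is
#' stated: gap-induction fraction 0.95, locus gap 10,000 bp, placement
#' probability 0.90, assembly flank 15,000 bp, half-length fraction 0.5.
#'
#' @param gap_induction_threshold gap-induction removal fraction.
#' @param locus_max_gap locus grouping gap (bp).
#' @param placement_threshold placement probability threshold.
#' @param assembly_flank alternative-assembly flank (bp).
#' @param half_length_fraction short-domain flag fraction.
#' @param expected_rvp_length expected RVP domain length (aa).
#' @param search a [search_params()].
#' @param ltr an [ltr_params()].
#' @param rules an [default_activity_rules()] rule set.
#' @param rng_seed integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(gap_induction_threshold = 0.95,
                            locus_max_gap = 10000,
                            placement_threshold = 0.90,
                            assembly_flank = 15000,
                            half_length_fraction = 0.5,
                            expected_rvp_length = 95,
                            search = search_params(),
                            ltr = ltr_params(),
                            rules = default_activity_rules(),
                            rng_seed = 1L) {
  cfg <- list(gap_induction_threshold = gap_induction_threshold,
              locus_max_gap = locus_max_gap,
              placement_threshold = placement_threshold,
              assembly_flank = assembly_flank,
              half_length_fraction = half_length_fraction,
              expected_rvp_length = expected_rvp_length,
              search = search, ltr = ltr, rules = rules,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "pipeline_config"
  cfg
}

# flat serialization: scalars and the numeric stage parameters round-trip
# through the key=value config format losslessly.
flatten_config <- function(cfg) {
  c(list(gap_induction_threshold = cfg$gap_induction_threshold,
         locus_max_gap = cfg$locus_max_gap,
         placement_threshold = cfg$placement_threshold,
         assembly_flank = cfg$assembly_flank,
         half_length_fraction = cfg$half_length_fraction,
         expected_rvp_length = cfg$expected_rvp_length,
         rng_seed = cfg$rng_seed),
    stats::setNames(cfg$search[c("gap_open", "gap_extend", "min_score",
                                 "merge_gap", "profile_threshold",
                                 "chunk_size", "chunk_overlap",
                                 "stop_score")],
                    paste0("search.", c("gap_open", "gap_extend",
                                        "min_score", "merge_gap",
                                        "profile_threshold", "chunk_size",
                                        "chunk_overlap", "stop_score"))),
    list(search.matrix = cfg$search$matrix,
         ltr.min_identity = cfg$ltr$min_identity,
         ltr.k = cfg$ltr$k,
         ltr.ltr_range = cfg$ltr$ltr_range,
         ltr.spacing_range = cfg$ltr$spacing_range))
}

#' Save a pipeline configuration to a flat key=value file
#' @param cfg a [pipeline_config()].
#' @param path output file.
#' @export
save_pipeline_config <- function(cfg, path) {
  write_config(flatten_config(cfg), path)
}

#' Load a pipeline configuration from a flat key=value file
#' @param path config file.
#' @return a [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  kv <- read_config(path)
  sp <- search_params(
    matrix = kv$search.matrix %||% "BLOSUM62",
    gap_open = kv$search.gap_open %||% 11,
    gap_extend = kv$search.gap_extend %||% 1,
    min_score = kv$search.min_score %||% 75,
    merge_gap = kv$search.merge_gap %||% 1000,
    profile_threshold = kv$search.profile_threshold %||% 30,
    chunk_size = kv$search.chunk_size %||% 12000,
    chunk_overlap = kv$search.chunk_overlap %||% 3000,
    stop_score = kv$search.stop_score %||% -10)
  lp <- ltr_params(ltr_range = kv$ltr.ltr_range %||% c(100, 1000),
                   min_identity = kv$ltr.min_identity %||% 0.85,
                   spacing_range = kv$ltr.spacing_range %||% c(1000, 15000),
                   k = kv$ltr.k %||% 12)
  pipeline_config(
    gap_induction_threshold = kv$gap_induction_threshold %||% 0.95,
    locus_max_gap = kv$locus_max_gap %||% 10000,
    placement_threshold = kv$placement_threshold %||% 0.90,
    assembly_flank = kv$assembly_flank %||% 15000,
    half_length_fraction = kv$half_length_fraction %||% 0.5,
    expected_rvp_length = kv$expected_rvp_length %||% 95,
    search = sp, ltr = lp, rng_seed = kv$rng_seed %||% 1)
}

#' Reference query proteins and domain profiles from a reference library
#'
#' Extracts the mature PR and RVT_1-like protein sequences of each
#' reference, returning search queries (the first reference's PR/RVT) and
#' PSSM profiles built from all references.
#'
#' @param references a [make_reference_set()] result.
#' @return list with `queries` (named protein vector: PR, RT) and
#'   `profiles` (list of PSSMs: RVP, RVT_1).
#' @export
reference_queries <- function(references) {
  aa <- vapply(references$sequences, function(nt)
    as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                       if.fuzzy.codon = "X")), character(1))
  pr <- substr(aa, GAG_CODONS + 1L, GAG_CODONS + PR_CODONS)
  rvt <- substr(aa, GAG_CODONS + PR_CODONS + 1L,
                GAG_CODONS + PR_CODONS + RVT_CODONS)
  list(queries = c(PR = unname(pr[1]), RT = unname(rvt[1])),
       profiles = list(RVP = build_pssm(pr, kind = "RVP"),
                       RVT_1 = build_pssm(rvt, kind = "RVT_1")))
}

#' Discovery stage: translated search + LTR/profile scan + locus grouping
#'
#' @param genome named nt vector.
#' @param queries named protein vector; names become feature kinds (e.g.
#'   PR, RT).
#' @param profiles list of PSSMs for the profile-scan route.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory: writes `annotations.gff3` and
#'   `loci.tsv`.
#' @return list with `annotations`, `candidates`, `loci`, `membership`.
#' @export
run_discover <- function(genome, queries, profiles = list(),
                         config = pipeline_config(), out_dir = NULL) {
  anns <- list()
  cands <- list()
  for (tid in names(genome)) {
    target <- genome[[tid]]
    for (qk in names(queries)) {
      hits <- translated_search(target, queries[[qk]], config$search,
                                target_id = tid, query_id = qk)
      if (!nrow(hits)) next
      merged <- merge_frame_hits(hits, config$search)
      qlen <- nchar(queries[[qk]])
      for (i in seq_len(nrow(merged))) {
        ext <- flush_extend(merged[i, ], qlen, nchar(target))
        anns[[length(anns) + 1L]] <- annotation_table(
          tid, ext$start, ext$end, ext$strand, qk, "translated_search",
          score = ext$score, clipped = ext$clipped)
      }
    }
    cand <- find_ltr_pairs(target, config$ltr, target_id = tid)
    cands[[length(cands) + 1L]] <- cand
    if (length(profiles)) {
      dom <- do.call(rbind, lapply(profiles, function(p)
        profile_scan(target, p, config$search, target_id = tid)))
      kept <- cooccurrence_filter(cand, dom)
      if (nrow(kept))
        anns[[length(anns) + 1L]] <- annotation_table(
          tid, kept$start, kept$end, kept$strand, kept$kind, "profile_scan",
          score = kept$score, clipped = FALSE)
    }
  }
  annotations <- do.call(rbind, c(list(annotation_table(score = numeric(0),
                                                        clipped = logical(0))),
                                  anns))
  candidates <- do.call(rbind, c(list(empty_candidates()), cands))
  loci <- group_loci(annotations, config$locus_max_gap)
  res <- list(annotations = annotations, candidates = candidates,
              loci = loci, membership = attr(loci, "membership"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (nrow(annotations))
      write_gff3(annotations, file.path(out_dir, "annotations.gff3"))
    utils::write.table(loci, file.path(out_dir, "loci.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  res
}

# strand-aware sequence extraction for an annotation row
extract_annotation_seq <- function(genome, ann_row) {
  s <- substr(genome[[ann_row$target]], ann_row$start + 1L, ann_row$end)
  if (ann_row$strand == "-") revcomp(s) else s
}

#' Classification stage: codon alignment, placement, motif triage
#'
#' Aligns the PR annotations together with the reference PR sequences,
#' builds the reference tree, places each annotation, reconciles locus
#' verdicts, extracts and classifies B1/C2 motifs, and tabulates them.
#'
#' @param genome named nt vector.
#' @param annotations discovery annotations (PR rows are used).
#' @param references a [make_reference_set()] result.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory: writes `classified.tsv`,
#'   `motif_table.tsv` and `reference_tree.nwk`.
#' @return list with `alignment`, `tree`, `classified` (per-annotation),
#'   `locus_verdicts`, `motif_calls`, `motif_table`.
#' @export
run_classify_motifs <- function(genome, annotations, references,
                                config = pipeline_config(), out_dir = NULL) {
  pr_ann <- annotations[annotations$kind %in% c("PR", "RVP"), , drop = FALSE]
  empty <- list(alignment = NULL, tree = NULL,
                classified = data.frame(), locus_verdicts = data.frame(),
                motif_calls = data.frame(), motif_table = data.frame())
  if (!nrow(pr_ann)) return(empty)
  qseqs <- vapply(seq_len(nrow(pr_ann)), function(i)
    extract_annotation_seq(genome, pr_ann[i, ]), character(1))
  names(qseqs) <- sprintf("q%03d", seq_along(qseqs))

  ref_pr_nt <- vapply(references$sequences, function(nt)
    substr(nt, GAG_CODONS * 3L + 1L, (GAG_CODONS + PR_CODONS) * 3L),
    character(1))
  names(ref_pr_nt) <- paste0("ref_", names(references$sequences))

  ca <- align_codon_aware(c(ref_pr_nt, qseqs), guide = names(ref_pr_nt)[1])
  ref_ids <- names(ref_pr_nt)

  # curation: drop query rows owning insertions that gap >= threshold of
  # the alignment rows (rare-insertion outliers), then re-align
  kept_rows <- gap_induction_filter(ca$aa, config$gap_induction_threshold)
  dropped <- setdiff(attr(kept_rows, "removed"), ref_ids)
  if (length(dropped)) {
    drop_idx <- match(dropped, names(qseqs))
    qseqs <- qseqs[-drop_idx]
    pr_ann <- pr_ann[-drop_idx, , drop = FALSE]
    if (!nrow(pr_ann)) return(empty)
    ca <- align_codon_aware(c(ref_pr_nt, qseqs),
                            guide = names(ref_pr_nt)[1])
  }

  ref_ca <- align_codon_aware(ref_pr_nt)
  rt <- build_reference_tree(
    ref_ca$aa,
    labels = data.frame(id = names(ref_pr_nt),
                        clade = references$labels$clade,
                        stringsAsFactors = FALSE))
  engine <- placement_engine(rt)

  verdicts <- character(length(qseqs))
  weights <- numeric(length(qseqs))
  for (i in seq_along(qseqs)) {
    prot <- gsub("[-!]", "", ca$aa[[names(qseqs)[i]]])
    prot <- gsub("\\*", "X", prot)
    pl <- place_query(rt, prot, engine = engine, query_id = names(qseqs)[i])
    verdicts[i] <- classify_placement(pl, rt, config$placement_threshold)
    weights[i] <- pl$best_weight %||% NA_real_
  }
  classified <- cbind(pr_ann,
                      data.frame(seq_id = names(qseqs), verdict = verdicts,
                                 weight = weights, stringsAsFactors = FALSE))

  loci <- group_loci(pr_ann, config$locus_max_gap)
  membership <- attr(loci, "membership")
  lv <- lapply(seq_len(nrow(loci)), function(l) {
    rec <- reconcile_locus(verdicts[membership == l])
    data.frame(locus = loci$locus[l], verdict = rec$verdict,
               conflict = rec$conflict, stringsAsFactors = FALSE)
  })
  locus_verdicts <- do.call(rbind, lv)

  calls <- extract_motifs(ca, ref_ids)
  calls <- calls[!calls$id %in% ref_ids, , drop = FALSE]
  uninterrupted <- calls$interrupted == "none"
  calls$activity[uninterrupted] <- vapply(which(uninterrupted), function(i)
    classify_activity(calls$b1[i], calls$c2[i], config$rules)$activity,
    character(1))
  motif_table <- tabulate_motifs(calls, config$rules)

  res <- list(alignment = ca, tree = rt, classified = classified,
              locus_verdicts = locus_verdicts, motif_calls = calls,
              motif_table = motif_table)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(classified, file.path(out_dir, "classified.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(motif_table, file.path(out_dir, "motif_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ape::write.tree(rt$tree, file.path(out_dir, "reference_tree.nwk"))
  }
  res
}

#' Expression stage: counting, FPKM, grouped contrasts
#'
#' @param loci data.frame `id`, `target`, `start`, `end` plus grouping
#'   columns (e.g. `clade`, `b1`).
#' @param samples data.frame `sample`, `sam` (path), `condition`, and
#'   optionally `pair` and `sex`.
#' @param group_cols grouping columns for the contrasts.
#' @param config a [pipeline_config()].
#' @param paired logical; use the signed-rank branch with pairing keys.
#' @param out_dir optional directory: writes `expression.tsv`,
#'   `contrasts.tsv`.
#' @return list with `records` (ExpressionRecord rows) and `contrasts`.
#' @export
run_express <- function(loci, samples, group_cols = "motif_class",
                        config = pipeline_config(), paired = FALSE,
                        out_dir = NULL) {
  if (paired && is.null(samples$pair))
    stopf("paired design requires a 'pair' column in samples")
  recs <- list()
  for (s in seq_len(nrow(samples))) {
    cf <- count_fragments(samples$sam[s], loci)
    rec <- data.frame(locus = loci$id, sample = samples$sample[s],
                      condition = samples$condition[s],
                      count = unname(cf$counts),
                      fpkm = fpkm(unname(cf$counts), loci$end - loci$start,
                                  cf$library_size),
                      stringsAsFactors = FALSE)
    if (!is.null(samples$pair)) rec$pair <- samples$pair[s]
    if (!is.null(samples$sex)) rec$sex <- samples$sex[s]
    extra <- setdiff(names(loci), c("id", "target", "start", "end"))
    for (col in extra) rec[[col]] <- loci[[col]]
    if ("b1" %in% names(loci))
      rec$motif_class <- ifelse(loci$b1 %in% c("DTGAD", "DTGVD"),
                                loci$b1, "other")
    recs[[s]] <- rec
  }
  records <- do.call(rbind, recs)
  contrasts <- contrast_by_group(
    records, group_cols, unique(samples$condition)[1:2],
    paired = paired, pairing_col = if (paired) "pair" else NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(records, file.path(out_dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(contrasts, file.path(out_dir, "contrasts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(records = records, contrasts = contrasts)
}
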