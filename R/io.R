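# Standard-format plumbing: FASTA via Biostrings, GFF3 via rtracklayer,
# SAM written directly (headered, coordinate-sorted) and read via Rsamtools.

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @param type "dna" or "protein".
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param type "dna" or "protein".
#' @export
write_fasta <- function(seqs, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::DNAStringSet(unlist(seqs))
         else Biostrings::AAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Convert an annotation table to GRanges
#'
#' Internal 0-based half-open intervals become 1-based inclusive.
#' @param ann annotation data.frame (see [annotation_table()]).
#' @return `GRanges` with metadata columns.
#' @export
annotation_to_granges <- function(ann) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$target,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ifelse(ann$strand %in% c("+", "-"), ann$strand, "*"))
  meta <- ann[, setdiff(names(ann), c("target", "start", "end", "strand")),
              drop = FALSE]
  S4Vectors::mcols(gr) <- meta
  gr
}

#' Convert GRanges back to an annotation table
#' @param gr `GRanges`.
#' @return annotation data.frame with 0-based half-open intervals.
#' @export
granges_to_annotation <- function(gr) {
  meta <- as.data.frame(S4Vectors::mcols(gr), stringsAsFactors = FALSE)
  df <- data.frame(target = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "+"
  out <- cbind(df, meta)
  if (!"kind" %in% names(out) && "type" %in% names(out)) out$kind <- out$type
  class(out) <- c("erv_annotation", "data.frame")
  out
}

#' Write annotations as GFF3 (1-based inclusive)
#'
#' @param ann annotation data.frame.
#' @param path output file.
#' @export
write_gff3 <- function(ann, path) {
  gr <- annotation_to_granges(ann)
  meta <- S4Vectors::mcols(gr)
  if ("kind" %in% names(meta)) {
    meta$type <- meta$kind
    meta$kind <- NULL
  }
  S4Vectors::mcols(gr) <- meta
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file into an annotation table
#'
#' @param path GFF3 file.
#' @return annotation data.frame (0-based half-open).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ann <- granges_to_annotation(gr)
  if ("type" %in% names(ann)) {
    ann$kind <- as.character(ann$type)
    ann$type <- NULL
  }
  ann
}

#' Write single-end alignments as a coordinate-sorted SAM file
#'
#' @param reads data.frame with columns `qname`, `target`, `pos` (0-based
#'   leftmost), `seq`, and optionally `strand` and `mapped` (logical).
#' @param seqlens named integer vector of target lengths.
#' @param path output SAM path.
#' @export
write_sam <- function(reads, seqlens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (nm in names(seqlens))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, as.integer(seqlens[[nm]])), con)
  writeLines(sprintf("@PG\tID:ervscan\tPN:ervscan\tVN:%s",
                     as.character(utils::packageVersion("ervscan"))), con)
  if (nrow(reads)) {
    if (is.null(reads$strand)) reads$strand <- "+"
    o <- order(match(reads$target, names(seqlens)), reads$pos)
    reads <- reads[o, , drop = FALSE]
    flag <- ifelse(reads$strand == "-", 16L, 0L)
    lines <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                     reads$qname, flag, reads$target, reads$pos + 1L,
                     nchar(reads$seq), reads$seq)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read primary alignments from a SAM file
#'
#' Validates that the file is headered and coordinate-sorted (input error
#' otherwise), then parses via Rsamtools.
#'
#' @param path SAM file.
#' @return data.frame with columns `qname`, `flag`, `target`, `pos`
#'   (0-based), `width`.
#' @export
read_sam <- function(path) {
  head1 <- readLines(path, n = 1L)
  if (!length(head1) || !startsWith(head1, "@HD"))
    stopf("SAM input must be headered (missing @HD): %s", path)
  if (!grepl("SO:coordinate", head1))
    stopf("SAM input must be coordinate-sorted: %s", path)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "qwidth")))[[1]]
  keep <- !is.na(res$pos) &
    bitwAnd(res$flag, 4L) == 0L &     # mapped
    bitwAnd(res$flag, 256L) == 0L &   # primary
    bitwAnd(res$flag, 2048L) == 0L    # not supplementary
  df <- data.frame(qname = res$qname[keep], flag = res$flag[keep],
                   target = as.character(res$rname[keep]),
                   pos = res$pos[keep] - 1L, width = res$qwidth[keep],
                   stringsAsFactors = FALSE)
  if (is.unsorted(df$pos[order(df$target)] + 0))  # defensive double check
    df <- df[order(df$target, df$pos), , drop = FALSE]
  df
}

#' Write a flat key=value configuration file
#' @param config named list of scalars.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v) paste(as.character(v), collapse = ","),
                 character(1))
  writeLines(paste0(names(config), "=", vals), path)
  invisible(path)
}

#' Read a flat key=value configuration file
#' @param path config file.
#' @return named list; numeric-looking values are converted, comma-separated
#'   values become vectors.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- list()
  for (p in kv) {
    key <- trimws(p[1])
    val <- strsplit(trimws(p[2]), ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}
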