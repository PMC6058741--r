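#' @importFrom methods is
#' @importFrom stats setNames
NULL

# Internal coordinate convention: 0-based half-open [start, end) on the plus
# strand.  Conversion to 1-based inclusive happens only at GFF3/SAM boundaries.

DNA_BASES <- c("A", "C", "G", "T")

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so that seeded generators never perturb user code.
#'
#' @param seed integer seed (must be < 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a character DNA sequence
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTRYSWKMBDHVN]", toupper(x))
  if (any(bad))
    stopf("non-IUPAC characters in %s", what)
  invisible(toupper(x))
}

check_protein <- function(x, what = "protein") {
  bad <- grepl("[^ARNDCQEGHILKMFPSTWYVBJZX*-]", toupper(x))
  if (any(bad))
    stopf("non-amino-acid characters in %s", what)
  invisible(toupper(x))
}

#' Translate a nucleotide string in a given frame
#'
#' Frames 0-2 on the plus strand, with ambiguity codes rendered as `X` and
#' stop codons as `*`.  Trailing partial codons are dropped.
#'
#' @param x character DNA sequence.
#' @param frame integer 0, 1 or 2.
#' @return single character string of amino acids.
#' @keywords internal
translate_frame <- function(x, frame = 0L) {
  n <- nchar(x)
  len <- ((n - frame) %/% 3L) * 3L
  if (len < 3L) return("")
  sub <- substr(x, frame + 1L, frame + len)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "X"))
}

# interval gap between 0-based half-open [s1,e1) and [s2,e2): 0 when they
# overlap or touch, otherwise the number of bases strictly between them.
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

#' Annotation table constructor
#'
#' The common currency of the discovery stages: a data.frame of strand-aware
#' genomic intervals (0-based half-open) carrying feature kind and provenance.
#'
#' @param target target sequence id.
#' @param start,end 0-based half-open interval.
#' @param strand "+" or "-".
#' @param kind feature kind, e.g. "PR", "RT", "LTR", "element".
#' @param source source method, e.g. "translated_search", "profile_scan".
#' @param ... further columns recycled to length.
#' @return data.frame with class `erv_annotation`.
#' @export
annotation_table <- function(target = character(), start = integer(),
                             end = integer(), strand = character(),
                             kind = character(), source = character(), ...) {
  df <- data.frame(target = as.character(target), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   kind = as.character(kind), source = as.character(source),
                   ..., stringsAsFactors = FALSE)
  class(df) <- c("erv_annotation", "data.frame")
  df
}

# substitution matrix for translated search: BLOSUM62 with the stop symbol
# scoring -10 against everything (interrupted ORFs still align, penalized).
search_matrix <- function(name = "BLOSUM62", stop_score = -10) {
  m <- get(utils::data(list = name, package = "Biostrings",
                       envir = environment()))
  m["*", ] <- stop_score
  m[, "*"] <- stop_score
  m
}
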