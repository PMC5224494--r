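#' Normalize a nucleotide string to a target alphabet
#'
#' Uppercases the input and interconverts T/U so that the result is a pure
#' DNA (\code{ACGT}) or RNA (\code{ACGU}) string. All architecture, folding
#' and duplex operations in this package run on the RNA alphabet; inputs are
#' auto-converted at entry points.
#'
#' @param seq Character scalar over \code{A,C,G,T,U} (case-insensitive).
#' @param target Either \code{"DNA"} or \code{"RNA"}.
#' @param n_policy How to treat \code{N}: \code{"reject"} (default) errors at
#'   the first offending position; \code{"as_a"} maps \code{N} to \code{A}
#'   with a warning, for scanning-only operations where an arbitrary
#'   non-matching placeholder is acceptable.
#' @return Normalized character scalar of the same length.
#' @examples
#' normalize_alphabet("ttgcaa", "RNA")  # "UUGCAA"
#' normalize_alphabet("UACUAAC", "DNA") # "TACTAAC"
#' @export
normalize_alphabet <- function(seq, target = c("RNA", "DNA"),
                               n_policy = c("reject", "as_a")) {
  target <- match.arg(target)
  n_policy <- match.arg(n_policy)
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- toupper(seq)
  if (n_policy == "as_a" && grepl("N", s, fixed = TRUE)) {
    warning("N symbols mapped to A (n_policy = 'as_a')")
    s <- gsub("N", "A", s, fixed = TRUE)
  }
  bad <- regexpr("[^ACGTU]", s)
  if (bad > 0L) {
    stop(sprintf("invalid symbol '%s' at position %d (alphabet is ACGT/ACGU)",
                 substr(s, bad, bad), bad))
  }
  if (target == "RNA") chartr("T", "U", s) else chartr("U", "T", s)
}

#' Reverse complement of a nucleotide string
#'
#' Standard antiparallel complement; applying the function twice returns the
#' input (within one alphabet). Under \code{alphabet = "auto"} strings
#' containing U are complemented as RNA and all others as DNA; RNA pipelines
#' working with U-free strings should pass \code{alphabet = "RNA"}
#' explicitly, since the automatic rule cannot distinguish a U-free RNA
#' string from DNA.
#'
#' @param seq Character scalar over \code{A,C,G,T,U} (case-insensitive).
#' @param alphabet \code{"auto"} (default), \code{"DNA"} or \code{"RNA"}.
#' @return Reverse-complemented uppercase string.
#' @examples
#' reverse_complement("AG") # "CT"
#' @export
reverse_complement <- function(seq, alphabet = c("auto", "DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- toupper(seq)
  bad <- regexpr("[^ACGTU]", s)
  if (bad > 0L) {
    stop(sprintf("invalid symbol '%s' at position %d", substr(s, bad, bad), bad))
  }
  dna <- switch(alphabet, DNA = TRUE, RNA = FALSE,
                auto = !grepl("U", s, fixed = TRUE))
  comp <- if (dna) chartr("ACGTU", "TGCAA", s) else chartr("ACGUT", "UGCAA", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Base composition of a nucleotide string
#'
#' Counts of A/C/G/T+U (T and U are pooled so that DNA- and RNA-alphabet
#' strings with the same underlying bases compare equal).
#'
#' @param seq Character scalar.
#' @return Named integer vector with elements \code{A}, \code{C}, \code{G},
#'   \code{TU}.
#' @export
base_composition <- function(seq) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  c(A = sum(s == "A"), C = sum(s == "C"), G = sum(s == "G"),
    TU = sum(s == "T" | s == "U"))
}

# split a normalized sequence into a character vector, "" -> character(0)
seq_chars <- function(seq) {
  if (nchar(seq) == 0L) return(character(0))
  strsplit(seq, "", fixed = TRUE)[[1L]]
}

is_pyrimidine <- function(chars) chars %in% c("C", "U", "T")
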