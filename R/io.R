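#' Read and write FASTA / FASTQ
#'
#' Thin wrappers around Biostrings keeping plain named character vectors as
#' the package-level currency for sequences.
#'
#' @param path File path.
#' @return `read_fasta()` / `read_fastq()` return a named character vector of
#'   uppercase sequences (FASTQ qualities are not retained; the lariat scanner
#'   is quality-agnostic, as is the string search it reproduces).
#' @name fasta_io
NULL

#' @rdname fasta_io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname fasta_io
#' @param seqs Named character vector.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), filepath = path,
                              format = "fasta")
  invisible(path)
}

#' @rdname fasta_io
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname fasta_io
#' @param quals Optional named character vector of Phred+33 quality strings;
#'   defaults to maximum quality.
#' @export
write_fastq <- function(seqs, path, quals = NULL) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(chartr("U", "T", seqs))
  if (is.null(quals)) {
    quals <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  }
  q <- Biostrings::PhredQuality(Biostrings::BStringSet(unname(quals)))
  qx <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(qx, filepath = path)
  invisible(path)
}

#' Read splice loci from FASTA plus an anchor table
#'
#' The anchor table assigns each FASTA record its intron/exon boundaries:
#' columns \code{id}, \code{intron_start}, \code{intron_end},
#' \code{exon_end} (1-based inclusive positions within the record; the 3'ss
#' junction lies between \code{intron_end} and \code{intron_end + 1}).
#' Sequence before \code{intron_start} becomes upstream-exon context and
#' sequence after \code{exon_end} downstream-intron context.
#'
#' @param fasta_path FASTA file of locus records.
#' @param anchor_path TSV with a header line and the four columns above.
#' @param alphabet Target alphabet.
#' @return List of [splice_locus()] objects.
#' @export
read_loci <- function(fasta_path, anchor_path, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  seqs <- read_fasta(fasta_path)
  anchors <- utils::read.delim(anchor_path, stringsAsFactors = FALSE)
  need <- c("id", "intron_start", "intron_end", "exon_end")
  if (!all(need %in% names(anchors))) {
    stop("anchor table must have columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(anchors)), function(i) {
    a <- anchors[i, ]
    if (!a$id %in% names(seqs)) stop("no FASTA record for anchor id ", a$id)
    s <- seqs[[a$id]]
    splice_locus(
      locus_id = a$id,
      upstream_exon_seq = substr(s, 1L, a$intron_start - 1L),
      intron_seq = substr(s, a$intron_start, a$intron_end),
      exon_seq = substr(s, a$intron_end + 1L, a$exon_end),
      downstream_intron_seq = if (a$exon_end < nchar(s))
        substr(s, a$exon_end + 1L, nchar(s)) else "",
      alphabet = alphabet)
  })
}

#' Read a motif list file
#'
#' One motif per line; blank lines and lines starting with \code{#} ignored.
#'
#' @param path File path.
#' @param name Set name (defaults to the file base name).
#' @param polarity One of \code{"enhancer"}, \code{"silencer"},
#'   \code{"neutral"}.
#' @return A [motif_set()].
#' @export
read_motifs <- function(path, name = NULL,
                        polarity = c("neutral", "enhancer", "silencer")) {
  polarity <- match.arg(polarity)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  motif_set(if (is.null(name)) basename(path) else name, lines, polarity)
}

#' Write a data frame as a TSV report
#' @param df Data frame.
#' @param path Output path.
#' @export
write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
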