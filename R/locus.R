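#' Construct an intron-exon splice locus
#'
#' A \code{splice_locus} is the substrate of all 3' splice site architecture
#' operations: an exon together with its upstream intron (whose last two
#' nucleotides are the 3'ss AG) and optional upstream-exon / downstream-intron
#' context. All component sequences are normalized to one alphabet at
#' construction.
#'
#' Coordinates follow the signed 3'ss-anchored convention used throughout the
#' splicing literature: intron positions are negative with position -1 the
#' last intron nucleotide (the G of the 3'ss AG); exon positions are positive
#' with +1 the first exon nucleotide. There is no position 0. "BP-31" thus
#' denotes the branch adenine 31 nt upstream of the intron/exon junction.
#'
#' @param locus_id Character scalar identifier.
#' @param intron_seq Upstream intron, 5'->3', ending with the 3'ss
#'   dinucleotide; length >= 4.
#' @param exon_seq The exon whose 3'ss is analyzed.
#' @param upstream_exon_seq,downstream_intron_seq Optional flanking context
#'   (may be empty strings).
#' @param alphabet Target alphabet, \code{"RNA"} (default) or \code{"DNA"}.
#' @param allow_non_ag If \code{TRUE}, a locus whose intron does not end in
#'   AG is accepted but flagged; architecture operations refuse such loci.
#' @param covered_range Optional signed-coordinate two-vector recording the
#'   range of positions actually supported by primary data (e.g. a figure
#'   panel that prints only part of the intron). Informational.
#' @return An object of class \code{"splice_locus"}.
#' @seealso [signed_to_internal()], [site_region_seq()], [compute_agez()]
#' @export
splice_locus <- function(locus_id, intron_seq, exon_seq,
                         upstream_exon_seq = "", downstream_intron_seq = "",
                         alphabet = c("RNA", "DNA"), allow_non_ag = FALSE,
                         covered_range = NULL) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(locus_id), length(locus_id) == 1L, nzchar(locus_id))
  norm <- function(s) if (nchar(s) == 0L) "" else normalize_alphabet(s, alphabet)
  intron_seq <- norm(intron_seq)
  exon_seq <- norm(exon_seq)
  upstream_exon_seq <- norm(upstream_exon_seq)
  downstream_intron_seq <- norm(downstream_intron_seq)
  if (nchar(intron_seq) < 4L) stop("intron_seq must be at least 4 nt")
  if (nchar(exon_seq) < 1L) stop("exon_seq must be nonempty")
  terminal <- substr(intron_seq, nchar(intron_seq) - 1L, nchar(intron_seq))
  ag <- if (alphabet == "RNA") "AG" else "AG"
  non_ag <- !identical(terminal, ag)
  if (non_ag && !allow_non_ag) {
    stop(sprintf("intron of locus '%s' does not end in the 3'ss AG (found '%s'); ",
                 locus_id, terminal),
         "use allow_non_ag = TRUE to store it anyway")
  }
  structure(
    list(locus_id = locus_id,
         upstream_exon_seq = upstream_exon_seq,
         intron_seq = intron_seq,
         exon_seq = exon_seq,
         downstream_intron_seq = downstream_intron_seq,
         alphabet_tag = alphabet,
         non_ag_terminus = non_ag,
         covered_range = covered_range),
    class = "splice_locus")
}

#' @export
print.splice_locus <- function(x, ...) {
  cat(sprintf("<splice_locus '%s'> [%s]\n", x$locus_id, x$alphabet_tag))
  cat(sprintf("  intron: %d nt (ends ...%s)%s\n", nchar(x$intron_seq),
              substr(x$intron_seq, max(1L, nchar(x$intron_seq) - 5L), nchar(x$intron_seq)),
              if (x$non_ag_terminus) " [non-AG terminus]" else ""))
  cat(sprintf("  exon:   %d nt\n", nchar(x$exon_seq)))
  if (nchar(x$upstream_exon_seq)) {
    cat(sprintf("  upstream exon context: %d nt\n", nchar(x$upstream_exon_seq)))
  }
  if (nchar(x$downstream_intron_seq)) {
    cat(sprintf("  downstream intron context: %d nt\n", nchar(x$downstream_intron_seq)))
  }
  invisible(x)
}

#' Convert a signed 3'ss-anchored coordinate to an internal offset
#'
#' Maps the signed convention (see [splice_locus()]) onto a 0-based offset
#' into the stored intron (negative positions) or exon (positive positions).
#'
#' @param pos Integer signed coordinate(s); 0 is invalid.
#' @param locus A \code{splice_locus}.
#' @return A list with elements \code{component} ("intron" or "exon") and
#'   \code{offset} (0-based index into that component), vectorized over
#'   \code{pos}.
#' @export
signed_to_internal <- function(pos, locus) {
  stopifnot(inherits(locus, "splice_locus"), is.numeric(pos))
  pos <- as.integer(pos)
  if (any(pos == 0L)) stop("signed coordinate 0 does not exist")
  n_i <- nchar(locus$intron_seq); n_e <- nchar(locus$exon_seq)
  if (any(pos < -n_i) || any(pos > n_e)) {
    stop(sprintf("position out of range for locus '%s' (intron %d nt, exon %d nt)",
                 locus$locus_id, n_i, n_e))
  }
  comp <- ifelse(pos < 0L, "intron", "exon")
  off <- ifelse(pos < 0L, n_i + pos, pos - 1L)
  list(component = comp, offset = as.integer(off))
}

#' Nucleotide(s) at signed position(s) of a locus
#' @inheritParams signed_to_internal
#' @return Character vector of single bases.
#' @export
base_at <- function(pos, locus) {
  m <- signed_to_internal(pos, locus)
  s <- ifelse(m$component == "intron", locus$intron_seq, locus$exon_seq)
  substr(s, m$offset + 1L, m$offset + 1L)
}

#' Extract the sequence of a signed-coordinate region
#'
#' Returns the contiguous sequence spanning signed positions \code{from} to
#' \code{to} (inclusive; \code{from <= to}, both nonzero), concatenating
#' across the intron/exon junction as needed.
#'
#' @param locus A \code{splice_locus}.
#' @param from,to Signed coordinates.
#' @return Character scalar.
#' @export
site_region_seq <- function(locus, from, to) {
  stopifnot(from <= to, from != 0L, to != 0L)
  pos <- setdiff(seq.int(from, to), 0L)
  paste(base_at(pos, locus), collapse = "")
}
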