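#' Scan reads for lariat junctions by mismatch-tolerant 5'ss k-mer search
#'
#' A read spans the 2'-5' branch junction of an excised lariat if it contains
#' the intron 5'-end k-mer (Hamming distance <= \code{max_mm} at some offset)
#' while the bases preceding that offset do NOT continue the upstream exon --
#' otherwise the read is an ordinary unspliced or exon-intron read. Both
#' orientations are scanned; reverse-strand hits are reported on the
#' reverse-complemented read with an orientation flag. The mismatch metric is
#' Hamming distance (substitutions only, no indels).
#'
#' @param reads Named character vector of read sequences (DNA or RNA).
#' @param five_ss_kmer The intron 5'-end k-mer (15 or 20 nt typical).
#' @param max_mm Maximum mismatches (default 3).
#' @param exclude_prefix Terminal bases of the upstream exon; a hit whose
#'   preceding read bases match this suffix with Hamming distance <=
#'   \code{max_mm} over the comparable overlap is rejected. \code{NULL}
#'   disables the filter.
#' @param both_strands Scan reverse complements too (default TRUE).
#' @return Data frame of qualifying hits: \code{read_id}, \code{seq} (in hit
#'   orientation), \code{match_offset} (1-based), \code{k},
#'   \code{mismatches}, \code{orientation} (\code{"+"} or \code{"-"}). All
#'   qualifying offsets are reported.
#' @export
scan_reads <- function(reads, five_ss_kmer, max_mm = 3L,
                       exclude_prefix = NULL, both_strands = TRUE) {
  if (length(reads) == 0L) stop("empty read set")
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  kmer <- chartr("U", "T", toupper(five_ss_kmer))
  k <- nchar(kmer)
  reads_dna <- chartr("U", "T", toupper(reads))
  if (any(nchar(reads_dna) < k)) stop("k-mer longer than shortest read")
  excl <- if (is.null(exclude_prefix)) NULL else
    chartr("U", "T", toupper(exclude_prefix))

  scan_one_strand <- function(seqs, orientation) {
    hits <- .hamming_scan_cpp(unname(seqs), kmer, as.integer(max_mm))
    if (nrow(hits) == 0L) return(NULL)
    keep <- rep(TRUE, nrow(hits))
    if (!is.null(excl)) {
      for (i in seq_len(nrow(hits))) {
        s <- seqs[[hits$read[i]]]
        o <- hits$offset[i]
        ov <- min(o - 1L, nchar(excl))     # comparable overlap
        if (ov > 0L) {
          pre <- substr(s, o - ov, o - 1L)
          ex <- substr(excl, nchar(excl) - ov + 1L, nchar(excl))
          d <- sum(seq_chars(pre) != seq_chars(ex))
          if (d <= max_mm) keep[i] <- FALSE   # still looks like the exon
        }
      }
    }
    hits <- hits[keep, , drop = FALSE]
    if (nrow(hits) == 0L) return(NULL)
    data.frame(read_id = names(seqs)[hits$read],
               seq = unname(seqs[hits$read]),
               match_offset = hits$offset, k = k,
               mismatches = hits$mismatches,
               orientation = orientation, stringsAsFactors = FALSE)
  }
  out <- scan_one_strand(reads_dna, "+")
  if (both_strands) {
    rc <- vapply(reads_dna, reverse_complement, character(1))
    out <- rbind(out, scan_one_strand(rc, "-"))
  }
  if (is.null(out)) {
    out <- data.frame(read_id = character(0), seq = character(0),
                      match_offset = integer(0), k = integer(0),
                      mismatches = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Call a branch point from one lariat-junction read
#'
#' The \code{anchor_len} bases immediately 5' of the junction in the read are
#' matched exactly against the intron, except at the branch position itself
#' (the last anchor base), where the read may carry the diagnostic A>T
#' substitution introduced by reverse transcription across the 2'-5' bond:
#' the intron base there must be A and the read base A or T. Placements that
#' match at more than one intron position are reported as ambiguous, never
#' silently resolved.
#'
#' @param read One row of the [scan_reads()] output (a list or one-row data
#'   frame with \code{seq} and \code{match_offset}).
#' @param intron_seq The full intron, 5'->3', ending with the 3'ss AG.
#' @param anchor_len Anchor length (default 12; reads with fewer bases before
#'   the junction are refused).
#' @param min_anchor Minimum acceptable anchor (default 8).
#' @return A \code{branch_point_call}: \code{bp_pos} (signed, relative to the
#'   3'ss), \code{branch_base_observed} (\code{"A"} or \code{"T"}),
#'   \code{ambiguous} flag (with all candidate positions when TRUE), and
#'   \code{anchor}.
#' @export
call_bp <- function(read, intron_seq, anchor_len = 12L, min_anchor = 8L) {
  intron <- chartr("U", "T", toupper(intron_seq))
  s <- chartr("U", "T", toupper(read$seq))
  o <- read$match_offset
  if (o - 1L < min_anchor) stop("fewer than min_anchor bases precede the junction")
  al <- min(anchor_len, o - 1L)
  anchor <- substr(s, o - al, o - 1L)
  a <- seq_chars(anchor)
  n <- nchar(intron)
  ic <- seq_chars(intron)
  hits <- integer(0)
  for (st in seq_len(n - al + 1L)) {
    frag <- ic[st:(st + al - 1L)]
    # exact outside the branch base; branch base must be intron A, read A or T
    if (frag[al] != "A") next
    if (!(a[al] %in% c("A", "T"))) next
    if (all(frag[-al] == a[-al])) hits <- c(hits, st + al - 1L)
  }
  if (length(hits) == 0L) stop("anchor not found in intron")
  bp_internal <- hits
  bp_signed <- bp_internal - n - 1L
  structure(list(
    bp_pos = if (length(hits) == 1L) bp_signed else NA_integer_,
    candidates = bp_signed,
    ambiguous = length(hits) > 1L,
    branch_base_observed = a[al],
    anchor = anchor,
    upstream_anchor_len = al), class = "branch_point_call")
}

#' Aggregate branch point calls into a usage table
#'
#' @param calls List of \code{branch_point_call}s (ambiguous calls are
#'   counted separately, not assigned to a position).
#' @return Data frame sorted by position: \code{bp_pos}, \code{support},
#'   \code{fraction} (of unambiguous calls), \code{n_a}, \code{n_t}
#'   (observed branch bases); attribute \code{n_ambiguous}.
#' @export
aggregate_calls <- function(calls) {
  amb <- vapply(calls, `[[`, logical(1), "ambiguous")
  ok <- calls[!amb]
  if (length(ok) == 0L) {
    out <- data.frame(bp_pos = integer(0), support = integer(0),
                      fraction = numeric(0), n_a = integer(0),
                      n_t = integer(0))
    attr(out, "n_ambiguous") <- sum(amb)
    return(out)
  }
  pos <- vapply(ok, function(x) as.integer(x[["bp_pos"]]), integer(1))
  base <- vapply(ok, `[[`, character(1), "branch_base_observed")
  tab <- sort(unique(pos))
  out <- data.frame(
    bp_pos = tab,
    support = vapply(tab, function(p) sum(pos == p), integer(1)),
    n_a = vapply(tab, function(p) sum(pos == p & base == "A"), integer(1)),
    n_t = vapply(tab, function(p) sum(pos == p & base == "T"), integer(1)))
  out$fraction <- out$support / sum(out$support)
  out <- out[, c("bp_pos", "support", "fraction", "n_a", "n_t")]
  attr(out, "n_ambiguous") <- sum(amb)
  out
}

#' End-to-end lariat branch-point pipeline
#'
#' Convenience wrapper: scan reads for the intron 5'-end k-mer, call a branch
#' point from every qualifying hit, and aggregate usage.
#'
#' @inheritParams scan_reads
#' @param intron_seq Full intron sequence.
#' @param anchor_len Passed to [call_bp()].
#' @param k Length of the 5'ss k-mer taken from \code{intron_seq} (ignored if
#'   \code{five_ss_kmer} is given).
#' @param five_ss_kmer Optional explicit k-mer.
#' @return List with \code{hits}, \code{calls}, \code{usage}.
#' @export
lariat_pipeline <- function(reads, intron_seq, k = 20L, five_ss_kmer = NULL,
                            max_mm = 3L, exclude_prefix = NULL,
                            anchor_len = 12L) {
  intron <- chartr("U", "T", toupper(intron_seq))
  if (is.null(five_ss_kmer)) five_ss_kmer <- substr(intron, 1L, k)
  hits <- scan_reads(reads, five_ss_kmer, max_mm, exclude_prefix)
  calls <- list()
  for (i in seq_len(nrow(hits))) {
    cl <- try(call_bp(hits[i, ], intron, anchor_len), silent = TRUE)
    if (!inherits(cl, "try-error")) calls[[length(calls) + 1L]] <- cl
  }
  list(hits = hits, calls = calls, usage = aggregate_calls(calls))
}
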