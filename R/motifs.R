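#' Construct a splicing-regulatory motif set
#'
#' @param name Set name.
#' @param motifs Character vector of motifs over one alphabet; duplicates are
#'   collapsed.
#' @param polarity \code{"enhancer"}, \code{"silencer"} or \code{"neutral"}.
#' @return A \code{motif_set}.
#' @export
motif_set <- function(name, motifs,
                      polarity = c("neutral", "enhancer", "silencer")) {
  polarity <- match.arg(polarity)
  if (length(motifs) == 0L) stop("motif set must be nonempty")
  motifs <- unique(toupper(motifs))
  has_t <- any(grepl("T", motifs, fixed = TRUE))
  has_u <- any(grepl("U", motifs, fixed = TRUE))
  if (has_t && has_u) stop("mixed DNA/RNA alphabets in motif set")
  bad <- grepl("[^ACGTU]", motifs)
  if (any(bad)) stop("invalid motif(s): ", paste(motifs[bad], collapse = ", "))
  structure(list(name = name, motifs = motifs, polarity = polarity),
            class = "motif_set")
}

#' Count motif occurrences and density over a sequence
#'
#' Occurrences are counted at every start position, so overlapping hits all
#' count (the default; set \code{overlap = FALSE} for non-overlapping
#' left-to-right counting per motif). Two normalizations are reported:
#' \code{density} = hits per nucleotide of the scanned sequence, and
#' \code{coverage} = fraction of positions under at least one hit.
#'
#' @param seq Nucleotide string.
#' @param motifs A [motif_set()].
#' @param overlap Count overlapping occurrences (default TRUE).
#' @return A \code{density_report}: \code{seq_id}, \code{motif_set},
#'   \code{n_hits}, \code{density}, \code{coverage}.
#' @param seq_id Identifier for reporting.
#' @export
count_motifs <- function(seq, motifs, overlap = TRUE, seq_id = "seq") {
  stopifnot(inherits(motifs, "motif_set"))
  s <- toupper(seq)
  if (nchar(s) == 0L) stop("empty sequence")
  seq_rna <- grepl("U", s, fixed = TRUE)
  set_rna <- any(grepl("U", motifs$motifs, fixed = TRUE))
  set_dna <- any(grepl("T", motifs$motifs, fixed = TRUE))
  if ((seq_rna && set_dna) || (grepl("T", s, fixed = TRUE) && set_rna)) {
    stop("alphabet mismatch between sequence and motif set")
  }
  n <- nchar(s)
  covered <- logical(n)
  n_hits <- 0L
  for (m in motifs$motifs) {
    k <- nchar(m)
    if (k > n) next
    if (overlap) {
      starts <- which(vapply(seq_len(n - k + 1L),
                             function(i) substr(s, i, i + k - 1L) == m,
                             logical(1)))
    } else {
      starts <- integer(0)
      i <- 1L
      while (i <= n - k + 1L) {
        if (substr(s, i, i + k - 1L) == m) {
          starts <- c(starts, i); i <- i + k
        } else i <- i + 1L
      }
    }
    n_hits <- n_hits + length(starts)
    for (st in starts) covered[st:(st + k - 1L)] <- TRUE
  }
  structure(list(seq_id = seq_id, motif_set = motifs$name,
                 n_hits = n_hits, density = n_hits / n,
                 coverage = mean(covered)), class = "density_report")
}

#' Motif densities for several sequences as a data frame
#' @param seqs Named character vector.
#' @param motifs A [motif_set()].
#' @param overlap Passed to [count_motifs()].
#' @return Data frame with one row per sequence.
#' @export
motif_density_table <- function(seqs, motifs, overlap = TRUE) {
  do.call(rbind, lapply(names(seqs), function(id) {
    r <- count_motifs(seqs[[id]], motifs, overlap, seq_id = id)
    data.frame(seq_id = id, motif_set = r$motif_set, n_hits = r$n_hits,
               density = r$density, coverage = r$coverage,
               stringsAsFactors = FALSE)
  }))
}
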