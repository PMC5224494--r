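#' Compute the AG exclusion zone (AGEZ) of a 3' splice site
#'
#' The AGEZ is the AG-dinucleotide-free stretch between the branch point
#' region and the 3'ss AG; genuine branch points overwhelmingly lie within
#' it. Scanning starts at signed position -3 (immediately 5' of the 3'ss AG)
#' and proceeds 5'-ward for the nearest dinucleotide AG (A at p, G at p + 1).
#' The reported length is \code{|p| - 2}, i.e. the number of intron positions
#' strictly between the upstream AG and the 3'ss AG. If no AG occurs within
#' \code{max_scan} intron positions the zone is flagged open-ended and its
#' length reported as \code{max_scan - 2}.
#'
#' @param locus A [splice_locus()]; its intron must end in AG.
#' @param max_scan Maximum number of 3'-terminal intron positions scanned
#'   (default 200; capped at the intron length).
#' @return List with \code{agez_length}, \code{first_upstream_ag_pos} (signed
#'   position of the A, or \code{NA} if open-ended) and \code{open_ended}.
#' @export
compute_agez <- function(locus, max_scan = 200L) {
  stopifnot(inherits(locus, "splice_locus"))
  if (locus$non_ag_terminus) {
    stop("locus '", locus$locus_id, "' has a non-AG 3'ss terminus; ",
         "architecture operations are undefined")
  }
  n <- nchar(locus$intron_seq)
  max_scan <- as.integer(min(max_scan, n))
  if (max_scan < 4L) stop("max_scan must be at least 4")
  chars <- seq_chars(locus$intron_seq)
  # signed position p has index n + p + 1 (1-based)
  for (p in -3L:(-(max_scan - 1L))) {
    i <- n + p + 1L
    if (i < 2L) break
    if (chars[i] == "A" && chars[i + 1L] == "G") {
      return(list(agez_length = -p - 2L, first_upstream_ag_pos = p,
                  open_ended = FALSE))
    }
  }
  list(agez_length = max_scan - 2L, first_upstream_ag_pos = NA_integer_,
       open_ended = TRUE)
}

#' Annotate the polypyrimidine tract (PPT) within the AGEZ
#'
#' Two definitions are provided. \code{pure_run} (default): the longest
#' uninterrupted run of pyrimidines (C/U) inside the AGEZ interval
#' \code{[-(agez_length + 2) + 1, -3]}, ties broken toward the 3'-most run.
#' \code{interruption_tolerant}: the maximal-scoring contiguous segment under
#' +1 per pyrimidine / -2 per purine, required to start and end on a
#' pyrimidine (ties toward the 3'-most, then shortest, segment). Either way
#' a tract shorter than \code{min_len} (default 5) is reported as absent.
#'
#' @param locus A [splice_locus()].
#' @param mode \code{"pure_run"} or \code{"interruption_tolerant"}.
#' @param max_scan Passed to [compute_agez()].
#' @param min_len Minimum tract length.
#' @return A \code{ppt_annotation} list (\code{start}, \code{end} signed
#'   coordinates with \code{start < end < 0}, \code{length},
#'   \code{pyrimidine_fraction}, \code{uridine_fraction}, \code{mode}) or
#'   \code{NULL} if no qualifying tract exists.
#' @export
find_ppt <- function(locus, mode = c("pure_run", "interruption_tolerant"),
                     max_scan = 200L, min_len = 5L) {
  mode <- match.arg(mode)
  agez <- compute_agez(locus, max_scan)
  lo <- -(agez$agez_length + 2L) + 1L  # 5'-most AGEZ position
  hi <- -3L
  if (lo > hi) return(NULL)
  pos <- seq.int(lo, hi)
  chars <- base_at(pos, locus)
  pyr <- is_pyrimidine(chars)
  best <- NULL  # list(i, j) indices into pos
  if (mode == "pure_run") {
    r <- rle(pyr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= min_len)
    if (length(runs)) {
      len <- r$lengths[runs]
      # longest run; ties toward the 3'-most (largest start index)
      cand <- runs[len == max(len)]
      k <- cand[length(cand)]
      best <- list(i = starts[k], j = ends[k])
    }
  } else {
    n <- length(pos)
    sc <- ifelse(pyr, 1L, -2L)
    for (i in seq_len(n)) {
      if (!pyr[i]) next
      cs <- cumsum(sc[i:n])
      for (jj in which(pyr[i:n])) {
        j <- i + jj - 1L
        if (j - i + 1L < min_len) next
        s <- cs[jj]
        if (is.null(best) || s > best$score ||
            (s == best$score && (j > best$j ||
                                 (j == best$j && i > best$i)))) {
          best <- list(i = i, j = j, score = s)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  sel <- chars[best$i:best$j]
  structure(list(
    start = pos[best$i], end = pos[best$j],
    length = best$j - best$i + 1L,
    pyrimidine_fraction = mean(is_pyrimidine(sel)),
    uridine_fraction = mean(sel %in% c("U", "T")),
    mode = mode), class = "ppt_annotation")
}

#' Assemble the per-locus 3' splice site architecture record
#'
#' Bundles AGEZ, PPT and branch-candidate annotations into one record per
#' locus, mirroring a table with columns AGEZ / PPT length / BP SVM score.
#' The SVM score, when given, is an imported annotation from an external
#' predictor and is never computed here.
#'
#' @param locus A [splice_locus()].
#' @param bp_candidates List of branch candidates (see [branch_candidates()]),
#'   possibly empty.
#' @param svm_score Optional imported numeric score.
#' @param max_scan,ppt_mode Passed to the underlying annotators.
#' @return An object of class \code{splice_site_architecture}.
#' @export
assemble_architecture <- function(locus, bp_candidates = list(),
                                  svm_score = NA_real_, max_scan = 200L,
                                  ppt_mode = "pure_run") {
  agez <- compute_agez(locus, max_scan)
  ppt <- find_ppt(locus, ppt_mode, max_scan)
  structure(list(
    locus_id = locus$locus_id,
    agez_length = agez$agez_length,
    first_upstream_ag_pos = agez$first_upstream_ag_pos,
    open_ended = agez$open_ended,
    ppt = ppt,
    bp_candidates = bp_candidates,
    svm_bp_score = svm_score), class = "splice_site_architecture")
}

#' Tabulate architecture records as a TSV-ready data frame
#'
#' @param archs List of \code{splice_site_architecture} records.
#' @return Data frame with one row per locus. Duplicate locus ids are an
#'   error.
#' @export
architecture_table <- function(archs) {
  ids <- vapply(archs, `[[`, character(1), "locus_id")
  if (anyDuplicated(ids)) {
    stop("duplicate locus_id in batch: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  do.call(rbind, lapply(archs, function(a) {
    data.frame(
      locus_id = a$locus_id,
      agez = a$agez_length,
      first_ag_pos = if (is.na(a$first_upstream_ag_pos)) NA_integer_
                     else a$first_upstream_ag_pos,
      ppt_start = if (is.null(a$ppt)) NA_integer_ else a$ppt$start,
      ppt_end = if (is.null(a$ppt)) NA_integer_ else a$ppt$end,
      ppt_len = if (is.null(a$ppt)) NA_integer_ else a$ppt$length,
      pyr_frac = if (is.null(a$ppt)) NA_real_ else a$ppt$pyrimidine_fraction,
      u_frac = if (is.null(a$ppt)) NA_real_ else a$ppt$uridine_fraction,
      n_bp = length(a$bp_candidates),
      svm_bp_score = a$svm_bp_score,
      stringsAsFactors = FALSE)
  }))
}
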