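#' Probability-of-unpaired (PU) profile of an RNA segment
#'
#' Computes per-position single-strandedness over the exact Boltzmann
#' ensemble of nested secondary structures. Under the default
#' \code{pair_count} model every admissible pair (Watson-Crick or G:U
#' wobble) contributes energy \code{-epsilon} (kT units) and hairpin loops
#' contain at least \code{min_loop} unpaired bases; there is no lonely-pair
#' restriction. Inside/outside dynamic programming yields the pair
#' probabilities P(i,j); PU(i) is computed by an independent
#' constrained-inside recursion (position i forbidden to pair), so
#' \code{sum_j P(i,j) + PU(i) = 1} holds as a genuine numerical cross-check.
#'
#' A full nearest-neighbor energy backend is a pluggable extension point
#' (\code{model = "nearest_neighbor"} dispatches to a function registered via
#' \code{options(splicearch.nn_backend = )}); it is not required by any
#' analysis in this package and absent by default.
#'
#' @param seq RNA (or DNA; auto-converted) string, length 5..\code{max_len}.
#' @param model \code{"pair_count"} (default) or \code{"nearest_neighbor"}.
#' @param epsilon Pair energy in kT units (> 0 favors pairing); default 1.
#' @param min_loop Minimum hairpin loop size (default 3).
#' @param max_len Guard on sequence length (default 300; the exact outside
#'   sum is O(n^4) and double-precision partition functions overflow near
#'   n = 450 at epsilon = 1).
#' @param allow_gu Admit G:U wobble pairs (default TRUE).
#' @param seq_id Identifier stored in the profile.
#' @param segment Optional signed-coordinate two-vector labelling the
#'   profiled interval.
#' @return An \code{accessibility_profile}: \code{pu} (numeric vector in
#'   [0,1]), \code{pair_prob} (symmetric matrix), \code{Z}, plus metadata.
#' @export
pu_profile <- function(seq, model = c("pair_count", "nearest_neighbor"),
                       epsilon = 1.0, min_loop = 3L, max_len = 300L,
                       allow_gu = TRUE, seq_id = "seq", segment = NULL) {
  model <- match.arg(model)
  s <- normalize_alphabet(seq, "RNA")
  n <- nchar(s)
  if (n < 5L || n > max_len) {
    stop(sprintf("sequence length %d outside [5, %d]", n, max_len))
  }
  if (!is.finite(epsilon)) stop("invalid epsilon")
  if (model == "nearest_neighbor") {
    backend <- getOption("splicearch.nn_backend")
    if (is.null(backend)) {
      stop("no nearest-neighbor backend registered; ",
           "set options(splicearch.nn_backend = <function(seq)>) or use the ",
           "self-contained 'pair_count' model")
    }
    res <- backend(s)
  } else {
    res <- .pu_pair_count_cpp(s, epsilon, as.integer(min_loop),
                              isTRUE(allow_gu))
  }
  structure(list(seq_id = seq_id, seq = s,
                 segment = segment,
                 pu = as.numeric(res$pu),
                 pair_prob = res$pair_prob,
                 Z = res$Z,
                 model_tag = model,
                 epsilon = epsilon, min_loop = as.integer(min_loop)),
            class = "accessibility_profile")
}

#' Construct the accessibility analysis segment of a locus
#'
#' Builds the signed-coordinate window used for group-level PU comparisons:
#' the exon plus its stored flanking intron plus \code{pad} additional
#' nucleotides of outer context in each direction. \code{side} selects which
#' flank anchors the segment: \code{"upstream_3ss"} uses the upstream intron
#' (the 3'ss side), \code{"downstream_5ss"} the downstream intron (the 5'ss
#' side). A locus whose stored context cannot supply the requested pad is
#' refused with an informative error rather than silently truncated.
#'
#' @param locus A [splice_locus()].
#' @param side \code{"upstream_3ss"} or \code{"downstream_5ss"}.
#' @param pad Outer padding in nt (default 30).
#' @param intron_span Number of intron positions included (default: the whole
#'   stored flanking intron).
#' @return List with \code{interval} (signed two-vector), \code{seq}, and
#'   \code{region} (signed positions of the intronic sub-interval used for
#'   pooled comparisons on that side).
#' @export
segment_for_locus <- function(locus, side = c("upstream_3ss", "downstream_5ss"),
                              pad = 30L, intron_span = NULL) {
  side <- match.arg(side)
  n_e <- nchar(locus$exon_seq)
  if (side == "upstream_3ss") {
    n_i <- nchar(locus$intron_seq)
    span <- if (is.null(intron_span)) n_i else min(intron_span, n_i)
    # pad extends 5' beyond the included intron span
    if (span + pad > n_i + nchar(locus$upstream_exon_seq)) {
      stop(sprintf("locus '%s' too short for pad %d on the 3'ss side",
                   locus$locus_id, pad))
    }
    from <- -(span)                       # intron positions -span..-1
    pad_seq <- if (pad > 0L) {
      if (span + pad <= n_i) {
        substr(locus$intron_seq, n_i - span - pad + 1L, n_i - span)
      } else {
        extra <- span + pad - n_i
        ue <- locus$upstream_exon_seq
        paste0(substr(ue, nchar(ue) - extra + 1L, nchar(ue)),
               substr(locus$intron_seq, 1L, n_i - span))
      }
    } else ""
    seq <- paste0(pad_seq, site_region_seq(locus, from, n_e))
    list(interval = c(from - pad, n_e), seq = seq,
         region = seq.int(from, -1L))
  } else {
    n_d <- nchar(locus$downstream_intron_seq)
    if (n_d < pad + 1L) {
      stop(sprintf("locus '%s' has no usable downstream intron for pad %d",
                   locus$locus_id, pad))
    }
    # exon plus the stored downstream intron; signed positions continue +
    seq <- paste0(locus$exon_seq, locus$downstream_intron_seq)
    list(interval = c(1L, n_e + n_d), seq = seq,
         region = seq.int(n_e + 1L, n_e + n_d))
  }
}

#' Compare pooled PU values between two groups of profiles
#'
#' Pools position-specific PU values within a selected sub-interval of each
#' profile and compares the groups with the two-sided Wilcoxon-Mann-Whitney
#' test (exact null for combined n <= 25 without ties, normal approximation
#' with continuity and tie correction otherwise; see [wilcoxon_mw()]).
#'
#' @param profiles_a,profiles_b Nonempty lists of
#'   \code{accessibility_profile} objects.
#' @param region Either \code{NULL} (all positions) or, per profile, a
#'   function \code{f(profile) -> integer indices} selecting positions.
#' @param group_a_label,group_b_label Labels for reporting.
#' @return A \code{group_comparison}: group means, U statistic, two-sided p,
#'   sample sizes.
#' @export
compare_groups <- function(profiles_a, profiles_b, region = NULL,
                           group_a_label = "A", group_b_label = "B") {
  stopifnot(length(profiles_a) > 0L, length(profiles_b) > 0L)
  pool <- function(profiles) {
    unlist(lapply(profiles, function(p) {
      idx <- if (is.null(region)) seq_along(p$pu) else region(p)
      if (length(idx) == 0L) stop("empty region for profile ", p$seq_id)
      p$pu[idx]
    }))
  }
  a <- pool(profiles_a); b <- pool(profiles_b)
  w <- wilcoxon_mw(a, b)
  structure(list(group_a_label = group_a_label, group_b_label = group_b_label,
                 mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b),
                 statistic = w$U, p_value = w$p_two_sided,
                 test = "wilcoxon_mann_whitney"),
            class = "group_comparison")
}
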