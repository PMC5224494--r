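#' Specify a mutation of a wild-type hairpin sequence
#'
#' Edits are expressed in the signed hairpin numbering used for the ESL
#' (positions count nucleotides upstream of the 3'ss; the wild-type 25-mer
#' spans -85..-61, written 5'->3' from -85). Supported edit types:
#' substitutions, a deletion interval, or wholesale replacement (for
#' scrambled / reverse-complement panels).
#'
#' @param variant_id Character id.
#' @param subs Optional data frame with columns \code{pos} (signed), \code{ref},
#'   \code{alt}.
#' @param del Optional signed two-vector (inclusive interval to delete).
#' @param replacement Optional replacement string (used verbatim).
#' @param label Optional label for replacements (e.g. \code{"SCR"},
#'   \code{"RC"}).
#' @return A \code{mutation_spec}.
#' @export
mutation_spec <- function(variant_id, subs = NULL, del = NULL,
                          replacement = NULL, label = NULL) {
  structure(list(variant_id = variant_id, subs = subs, del = del,
                 replacement = replacement, label = label),
            class = "mutation_spec")
}

#' Apply a mutation spec to a wild-type sequence
#'
#' Reference symbols are verified against the wild type at the stated signed
#' positions before editing; a mismatch is an error naming the position
#' (guarding against coordinate bugs).
#'
#' @param wt Wild-type RNA string, written 5'->3'.
#' @param spec A [mutation_spec()].
#' @param pos5 Signed coordinate of the first (5'-most) base of \code{wt}
#'   (default -85, the ESL layout).
#' @return Edited RNA string.
#' @export
apply_mutation <- function(wt, spec, pos5 = -85L) {
  stopifnot(inherits(spec, "mutation_spec"))
  wt <- normalize_alphabet(wt, "RNA")
  if (!is.null(spec$replacement)) {
    return(normalize_alphabet(spec$replacement, "RNA"))
  }
  chars <- seq_chars(wt)
  idx_of <- function(pos) {
    i <- as.integer(pos) - as.integer(pos5) + 1L
    if (any(i < 1L | i > length(chars))) stop("edit position outside sequence")
    i
  }
  if (!is.null(spec$subs)) {
    for (r in seq_len(nrow(spec$subs))) {
      i <- idx_of(spec$subs$pos[r])
      ref <- normalize_alphabet(spec$subs$ref[r], "RNA")
      if (chars[i] != ref) {
        stop(sprintf("ref mismatch at position %d: wild type has %s, spec says %s",
                     spec$subs$pos[r], chars[i], ref))
      }
      chars[i] <- normalize_alphabet(spec$subs$alt[r], "RNA")
    }
  }
  if (!is.null(spec$del)) {
    i <- idx_of(min(spec$del)):idx_of(max(spec$del))
    chars <- chars[-i]
  }
  paste(chars, collapse = "")
}

#' Fold a hairpin-scale RNA and report its minimum-energy structure
#'
#' Under the default \code{pair_count} model the minimum-energy nested
#' structure maximizes the number of admissible pairs (Watson-Crick + G:U,
#' hairpin loops >= \code{min_loop}); its energy is \code{-epsilon * pairs}.
#' Traceback is deterministic: the 5'-most position is paired with its
#' smallest co-optimal partner, giving the 5'-most outermost pair among
#' co-optimal structures. Identical sequence and model always give identical
#' output.
#'
#' @param seq RNA (or DNA) string, length 10..200.
#' @param model \code{"pair_count"} or \code{"nearest_neighbor"} (pluggable;
#'   see [pu_profile()]).
#' @param epsilon Energy per pair in model units (default 1).
#' @param min_loop Minimum hairpin loop (default 3).
#' @param allow_gu Admit G:U wobble pairs (default TRUE). With wobble pairs
#'   disabled the admissible-pair set is closed under complementation, so
#'   the minimum energy is exactly invariant under reverse complement.
#' @param variant_id Identifier carried into the result.
#' @return A \code{hairpin_evaluation}: \code{variant_id}, \code{seq},
#'   \code{delta_g}, \code{n_pairs}, \code{structure} (dot-bracket),
#'   \code{model_tag}.
#' @export
fold_hairpin <- function(seq, model = c("pair_count", "nearest_neighbor"),
                         epsilon = 1.0, min_loop = 3L, allow_gu = TRUE,
                         variant_id = "seq") {
  model <- match.arg(model)
  s <- normalize_alphabet(seq, "RNA")
  n <- nchar(s)
  if (n < 10L || n > 200L) stop("sequence length must be in [10, 200]")
  if (model == "nearest_neighbor") {
    backend <- getOption("splicearch.nn_fold_backend")
    if (is.null(backend)) stop("no nearest-neighbor folding backend registered")
    res <- backend(s)
    dg <- res$delta_g; db <- res$structure; np <- res$n_pairs
  } else {
    res <- .nussinov_cpp(s, as.integer(min_loop), isTRUE(allow_gu))
    np <- res$n_pairs
    dg <- -epsilon * np
    db <- res$structure
  }
  structure(list(variant_id = variant_id, seq = s, delta_g = dg,
                 n_pairs = np, structure = db, model_tag = model,
                 epsilon = epsilon), class = "hairpin_evaluation")
}

#' Fold a mutation panel of a wild-type hairpin
#'
#' @param wt Wild-type sequence.
#' @param specs List of [mutation_spec()]s (a spec named \code{WT} with no
#'   edits may be included for the wild type).
#' @param ... Passed to [fold_hairpin()].
#' @inheritParams apply_mutation
#' @return Named list of \code{hairpin_evaluation}s.
#' @export
fold_panel <- function(wt, specs, pos5 = -85L, ...) {
  evals <- lapply(specs, function(sp) {
    fold_hairpin(apply_mutation(wt, sp, pos5), variant_id = sp$variant_id, ...)
  })
  stats::setNames(evals, vapply(specs, `[[`, character(1), "variant_id"))
}

#' Correlate hairpin stability with measured exon inclusion
#'
#' Pearson correlation (with the two-sided t-based p-value) between predicted
#' free energies and inclusion levels of matched variants; Spearman's rho is
#' reported alongside. A positive r means less stable hairpins (higher
#' delta G) associate with higher inclusion.
#'
#' @param evals List of \code{hairpin_evaluation}s.
#' @param inclusion Data frame with columns \code{variant_id} and
#'   \code{inclusion_pct}.
#' @return List with \code{r}, \code{p}, \code{rho}, \code{rho_p}, \code{n}.
#' @export
stability_inclusion_correlation <- function(evals, inclusion) {
  ids <- vapply(evals, `[[`, character(1), "variant_id")
  if (!all(ids %in% inclusion$variant_id)) {
    stop("unmatched variant ids: ",
         paste(setdiff(ids, inclusion$variant_id), collapse = ", "))
  }
  dg <- vapply(evals, `[[`, numeric(1), "delta_g")
  inc <- inclusion$inclusion_pct[match(ids, inclusion$variant_id)]
  if (length(dg) < 3L) stop("need at least 3 matched variants")
  if (stats::sd(dg) == 0 || stats::sd(inc) == 0) {
    stop("zero variance in delta G or inclusion")
  }
  pe <- pearson_cor(dg, inc)
  sp <- spearman_cor(dg, inc)
  list(r = pe$r, p = pe$p, rho = sp$rho, rho_p = sp$p, n = length(dg))
}
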