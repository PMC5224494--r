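#' The U2 snRNA guide used for branch point duplex scoring
#'
#' The branch-recognition box of human U2 snRNA ("AUGAUG" when read 3'->5')
#' is stored 5'->3' as \code{GUAGUA}, flanked by the adjacent single-stranded
#' U2 regions used for extended pairing counts. All three parts are
#' overridable so that alternative guide annotations can be scored without
#' code changes.
#'
#' @param core BP-interacting box, 5'->3' RNA.
#' @param extended_5p,extended_3p Flanking single-stranded U2 sequence 5' and
#'   3' of the core (5'->3' RNA). The scanning template is
#'   \code{extended_5p + core + extended_3p}.
#' @param bond_table Named numeric vector of hydrogen bonds per pair type:
#'   \code{GC} (Watson-Crick G:C), \code{AU} (Watson-Crick A:U), \code{GU}
#'   (wobble). The default counts wobble pairs as two bonds.
#' @return An object of class \code{u2_guide}.
#' @export
u2_guide <- function(core = "GUAGUA",
                     extended_5p = "AUCAAGU",
                     extended_3p = "UCUGUUC",
                     bond_table = c(GC = 3, AU = 2, GU = 2)) {
  core <- normalize_alphabet(core, "RNA")
  extended_5p <- if (nchar(extended_5p)) normalize_alphabet(extended_5p, "RNA") else ""
  extended_3p <- if (nchar(extended_3p)) normalize_alphabet(extended_3p, "RNA") else ""
  stopifnot(nchar(core) > 0, all(c("GC", "AU", "GU") %in% names(bond_table)))
  structure(list(core = core, extended_5p = extended_5p,
                 extended_3p = extended_3p, bond_table = bond_table),
            class = "u2_guide")
}

# hydrogen bonds for one window base (5'->3') facing one guide base, both RNA
.pair_bonds <- function(w, g, bond_table) {
  key <- paste0(w, g)
  bonds <- c(GC = unname(bond_table["GC"]), CG = unname(bond_table["GC"]),
             AU = unname(bond_table["AU"]), UA = unname(bond_table["AU"]),
             GU = unname(bond_table["GU"]), UG = unname(bond_table["GU"]))
  out <- bonds[key]
  out[is.na(out)] <- 0
  unname(out)
}

#' Score one U2 base-pairing register against an intron window
#'
#' Aligns the guide antiparallel to the window with the branch nucleotide
#' bulged out (excluded from pairing; the flanking duplex closes around it).
#' In the canonical register (\code{shift = 0}) the guide core pairs with the
#' five window positions 5' of the bulge and the first position 3' of it --
#' the geometry of the canonical UACUAAC / GUAGUA duplex. Positive shifts
#' slide the guide footprint toward the window 3' end (the intron 3' end),
#' negative shifts toward the 5' end. The extended count adds the
#' single-stranded guide flanks by helix propagation: pairs are accrued
#' outward from each core edge only while consecutive pairs keep forming,
#' stopping at the first non-pairing position (mismatches inside the boxed
#' core contribute zero bonds but do not truncate the core count).
#'
#' @param window RNA string (a branch-point region extracted 5'->3').
#' @param guide A [u2_guide()].
#' @param shift Integer register shift.
#' @param bulge_offset 1-based position of the bulged (branch) nucleotide in
#'   \code{window}.
#' @return An object of class \code{u2_register}: \code{shift},
#'   \code{bulge_offset}, \code{hbonds_core}, \code{hbonds_extended},
#'   \code{pairing} (per-core-position labels \code{WC}/\code{wobble}/
#'   \code{mismatch}) and \code{bulged_base}.
#' @examples
#' score_duplex("UACUAAC", u2_guide(), shift = 0, bulge_offset = 6)
#' @export
score_duplex <- function(window, guide = u2_guide(), shift = 0L,
                         bulge_offset) {
  stopifnot(inherits(guide, "u2_guide"))
  window <- normalize_alphabet(window, "RNA")
  n <- nchar(window)
  b <- as.integer(bulge_offset)
  if (b < 1L || b > n) stop("bulge_offset outside window")
  wc <- seq_chars(window)
  wprime <- wc[-b]                       # window with the bulge excised
  k <- nchar(guide$core)
  # canonical core footprint in excised coordinates: (b - k + 1) .. b,
  # i.e. the k - 1 positions 5' of the bulge plus the one 3' of it
  f0 <- b - k + 1L + as.integer(shift)
  f1 <- f0 + k - 1L
  if (f0 < 1L || f1 > length(wprime)) {
    stop(sprintf("window too short for core footprint at shift %+d", shift))
  }
  core_rev <- rev(seq_chars(guide$core))     # guide 3'->5', faces window 5'->3'
  core_b <- .pair_bonds(wprime[f0:f1], core_rev, guide$bond_table)
  labels <- ifelse(core_b == 0, "mismatch",
            ifelse(.is_wobble(wprime[f0:f1], core_rev), "wobble", "WC"))
  # extended flanks: e3 (3' of core) reaches the window 5' side, e5 the 3' side.
  # Walking 5'-ward on the window walks 3'-ward along the guide (antiparallel),
  # so e3 is consumed first-base-first; e5 is consumed from its 3' end.
  # Extension models helix propagation: it proceeds outward from each core
  # edge only while consecutive pairs keep forming, stopping at the first
  # non-pairing position (or the window/template end).
  ext_b <- 0
  e3 <- seq_chars(guide$extended_3p)
  for (i in seq_along(e3)) {
    p <- f0 - i
    if (p < 1L) break
    b3 <- .pair_bonds(wprime[p], e3[i], guide$bond_table)
    if (b3 == 0) break
    ext_b <- ext_b + b3
  }
  e5_rev <- rev(seq_chars(guide$extended_5p))
  for (i in seq_along(e5_rev)) {
    p <- f1 + i
    if (p > length(wprime)) break
    b5 <- .pair_bonds(wprime[p], e5_rev[i], guide$bond_table)
    if (b5 == 0) break
    ext_b <- ext_b + b5
  }
  structure(list(shift = as.integer(shift), bulge_offset = b,
                 bulged_base = wc[b],
                 hbonds_core = sum(core_b),
                 hbonds_extended = sum(core_b) + ext_b,
                 pairing = labels), class = "u2_register")
}

.is_wobble <- function(w, g) (w == "G" & g == "U") | (w == "U" & g == "G")

#' Enumerate U2 base-pairing registers for a branch window
#'
#' Scores every (shift, bulge) combination and reports the best register:
#' maximal \code{hbonds_extended}, ties broken by smaller absolute shift,
#' then by the more negative shift, then by the 5'-most bulge.
#'
#' @inheritParams score_duplex
#' @param shifts Integer vector of register shifts (default \code{-2:2}).
#' @param bulge_policy \code{"fixed"} scores only \code{bulge_offset};
#'   \code{"any_adenosine"} additionally admits every adenosine in the window
#'   as the bulged nucleophile.
#' @return List with \code{registers} (one \code{u2_register} per
#'   combination, in deterministic order) and \code{best}.
#' @export
enumerate_registers <- function(window, guide = u2_guide(), shifts = -2:2,
                                bulge_offset,
                                bulge_policy = c("fixed", "any_adenosine")) {
  bulge_policy <- match.arg(bulge_policy)
  if (length(shifts) == 0L) stop("empty shift range")
  window <- normalize_alphabet(window, "RNA")
  bulges <- as.integer(bulge_offset)
  if (bulge_policy == "any_adenosine") {
    bulges <- sort(unique(c(bulges, which(seq_chars(window) == "A"))))
  }
  # a bulge is admissible only if the core footprint fits at every shift
  k <- nchar(guide$core)
  nw <- nchar(window) - 1L
  bulges <- bulges[bulges - k + 1L + min(shifts) >= 1L &
                   bulges + max(shifts) <= nw]
  if (length(bulges) == 0L) stop("no admissible bulge for the given shifts")
  regs <- list()
  for (bu in bulges) for (s in sort(shifts)) {
    regs[[length(regs) + 1L]] <- score_duplex(window, guide, s, bu)
  }
  key <- vapply(regs, function(r) {
    c(-r$hbonds_extended, abs(r$shift), r$shift, r$bulge_offset)
  }, numeric(4))
  best <- regs[[order(key[1, ], key[2, ], key[3, ], key[4, ])[1L]]]
  list(registers = regs, best = best)
}

#' Classify a branch point heptamer against the UNA consensus
#'
#' The optimal human branch consensus carries a uridine two positions 5' of
#' the branch adenine ("UNA"). A heptamer covering positions -5..+1 around
#' the branch base (branch at the second-to-last position, the default) is
#' \code{"canonical_UNA"} iff position -2 is U and position 0 is A.
#'
#' @param heptamer RNA/DNA string of width >= 3 covering at least -2..0.
#' @param branch_index 1-based index of the branch base within
#'   \code{heptamer}; default \code{nchar(heptamer) - 1} (the -5..+1 layout).
#' @return \code{"canonical_UNA"} or \code{"noncanonical"}.
#' @export
classify_bp_consensus <- function(heptamer, branch_index = nchar(heptamer) - 1L) {
  h <- normalize_alphabet(heptamer, "RNA")
  if (nchar(h) < 3L || branch_index < 3L || branch_index > nchar(h)) {
    stop("heptamer must cover positions -2..0 around the branch base")
  }
  ch <- seq_chars(h)
  if (ch[branch_index - 2L] == "U" && ch[branch_index] == "A") {
    "canonical_UNA"
  } else {
    "noncanonical"
  }
}

#' Build branch candidate records for stated branch positions of a locus
#'
#' For each signed branch position, extracts the -5..+1 heptamer and a wider
#' register-scanning window, classifies the consensus, and records the
#' canonical (shift 0) and best register.
#'
#' @param locus A [splice_locus()].
#' @param bp_positions Integer vector of signed branch adenine positions
#'   (negative, within the intron).
#' @param guide A [u2_guide()].
#' @param shifts Register shifts to explore.
#' @param window_up,window_down Number of positions extracted 5' and 3' of
#'   the branch base for register scanning (clipped at the sequence ends).
#' @return List of \code{branch_candidate} records.
#' @export
branch_candidates <- function(locus, bp_positions, guide = u2_guide(),
                              shifts = -2:2, window_up = 14L, window_down = 9L) {
  n_i <- nchar(locus$intron_seq)
  lapply(as.integer(bp_positions), function(p) {
    stopifnot(p < -2L, p >= -n_i)
    up <- min(window_up, n_i + p)          # positions available 5' of the BP
    dn <- window_down
    to <- p + dn
    if (to >= 0L) to <- to + 1L            # skip nonexistent position 0
    win <- site_region_seq(locus, p - up, to)
    bo <- up + 1L
    hept <- site_region_seq(locus, p - 5L, p + 1L)
    enum <- enumerate_registers(win, guide, shifts, bulge_offset = bo)
    canonical <- score_duplex(win, guide, 0L, bo)
    structure(list(
      pos = p,
      heptamer = hept,
      has_minus2_pyrimidine = is_pyrimidine(base_at(p - 2L, locus)),
      consensus = classify_bp_consensus(hept),
      canonical_register = canonical,
      best_register = enum$best,
      registers = enum$registers), class = "branch_candidate")
  })
}

#' Tabulate register scans as a TSV-ready data frame
#' @param candidates List from [branch_candidates()].
#' @param locus_id Optional id column value.
#' @return Data frame with one row per (candidate, register).
#' @export
register_table <- function(candidates, locus_id = NA_character_) {
  do.call(rbind, lapply(candidates, function(cand) {
    do.call(rbind, lapply(cand$registers, function(r) {
      data.frame(locus = locus_id, bp_pos = cand$pos, shift = r$shift,
                 bulge_offset = r$bulge_offset,
                 hbonds_core = r$hbonds_core, hbonds_ext = r$hbonds_extended,
                 pairing = paste(r$pairing, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }))
}
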