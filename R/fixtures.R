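#' Printed ESL replacement 25-mers
#'
#' The scrambled (SCR) and reverse-complement (RC) hairpin replacement
#' sequences of the ESL mutation panel, as printed (DNA alphabet in the
#' source; returned as RNA here). The wild-type ESL 25-mer is defined
#' operationally as the reverse complement of the RC sequence.
#'
#' @return Character scalar (RNA).
#' @name esl_sequences
NULL

#' @rdname esl_sequences
#' @export
esl_scr_25mer <- function() normalize_alphabet("gactacttttctacttacaggataa", "RNA")

#' @rdname esl_sequences
#' @export
esl_rc_25mer <- function() normalize_alphabet("ttgcaaagagacaatttgtttgcaa", "RNA")

#' @rdname esl_sequences
#' @export
wt_esl <- function() reverse_complement(esl_rc_25mer())

#' The ESL mutation panel
#'
#' Eleven variants of the stem loop upstream of the exon Ab branch cluster
#' (positions -85..-61; the wild type written 5'->3' from -85): the wild
#' type; the internal-loop C>G substitutions at -68 and -78 (singly and
#' combined) predicted to stabilize the hairpin; the 7-nt deletion of the 5'
#' stem (-85..-79); the stem G/C swap at -64/-63 preserving
#' self-complementarity; the loop substitutions C-68>A and the -77/-76
#' double substitution; a further hyperstabilizing double; and the wholesale
#' scrambled (SCR) and reverse-complement (RC) replacements.
#'
#' @return Named list of [mutation_spec()]s, wild type first.
#' @export
esl_mutation_panel <- function() {
  sub1 <- function(pos, ref, alt) data.frame(pos = pos, ref = ref, alt = alt,
                                             stringsAsFactors = FALSE)
  specs <- list(
    mutation_spec("WT"),
    mutation_spec("G-68", subs = sub1(-68, "C", "G")),
    mutation_spec("G-78", subs = sub1(-78, "C", "G")),
    mutation_spec("G-68_G-78", subs = rbind(sub1(-68, "C", "G"),
                                            sub1(-78, "C", "G"))),
    mutation_spec("del-79-85", del = c(-85, -79)),
    mutation_spec("swap-63-64", subs = rbind(sub1(-64, "G", "C"),
                                             sub1(-63, "C", "G"))),
    mutation_spec("A-68", subs = sub1(-68, "C", "A")),
    mutation_spec("G-76_G-77", subs = rbind(sub1(-77, "A", "G"),
                                            sub1(-76, "A", "G"))),
    mutation_spec("G-76_G-68", subs = rbind(sub1(-76, "A", "G"),
                                            sub1(-68, "C", "G"))),
    mutation_spec("SCR", replacement = esl_scr_25mer(), label = "SCR"),
    mutation_spec("RC", replacement = esl_rc_25mer(), label = "RC"))
  stats::setNames(specs, vapply(specs, `[[`, character(1), "variant_id"))
}

# Synthetic stand-in for the intron 2 / exon Ab locus. The primary source
# prints the upstream sequence only in a figure panel; this 120-nt intron was
# designed once (fixed search, frozen here) to satisfy every architecture
# fact stated in the running text and summary table: AGEZ 31 (nearest
# upstream AG with its A at -33), pure-run PPT of 25 (-28..-4), four branch
# adenines at -40/-35/-33/-31 tiling four AGs, no pyrimidine at any BP-2,
# the wild-type ESL 25-mer at -85..-61, a GUAAGU 5'ss, and shifted U2
# registers carrying more than twice the canonical hydrogen bonds at every
# BP. It is a synthetic fixture, not the genomic sequence.
.AB_INTRON <- paste0(
  "GUAAGUUGUGCCCUCCCCAGUAUGUGUAGCCGUCUUUGCAAACAAAUUGUCUCUUUGCAA",
  "CGUCCGAGAUUUCAUGGGGCAGAGGAGAGAAAUCCCUUCUUUCCUCCCUCCUUCCUCAAG")
.AB_EXON <- "CCUUGAGAGCACUCCAGUCCAGGCGAGGUAUCCACGACGAUACGACUCGGCUAGCAAACGCGCGGUU"
.AB_UPSTREAM_EXON <- "UUUACACUUAGGCGCGCAUGAAUGACUCUAGCGAAACUUCUUUGGAACAC"
.AB_DOWNSTREAM_INTRON <-
  "GUAAGUAGGACUUAAUAAGCGCUCCUAAAAACUGCGUACAAUACGCAGAG"

#' Synthetic exon Ab-like locus
#'
#' A deterministic, clearly synthetic stand-in for the U2AF1 intron 2 /
#' exon Ab 3' splice site, carrying the experimentally established
#' architecture (AGEZ 31, pure PPT 25, a cluster of four weak branch
#' adenines within [-40, -30] including -31 and -33, none with a pyrimidine
#' at BP-2, and the ESL at -85..-61 whose sequence is the reverse complement
#' of the printed RC 25-mer). See the package vignette for the design
#' constraints and their provenance.
#'
#' @return A [splice_locus()].
#' @export
u2af1_ab_synthetic_locus <- function() {
  splice_locus("U2AF1_exonAb_synthetic", .AB_INTRON, .AB_EXON,
               upstream_exon_seq = .AB_UPSTREAM_EXON,
               downstream_intron_seq = .AB_DOWNSTREAM_INTRON,
               covered_range = c(-120L, 67L))
}

#' Branch adenine positions of the synthetic exon Ab-like locus
#' @return Integer vector (signed coordinates), 5' to 3'.
#' @export
u2af1_ab_bp_positions <- function() c(-40L, -35L, -33L, -31L)

#' Exon Ab-like exon and its enhancer-gaining hybrid
#'
#' The hybrid substitutes a short internal segment of the synthetic exon so
#' that a GAA trinucleotide (a potent exonic splicing enhancer core) is
#' created, mirroring an exon-segment swap that converts a repressed exon
#' toward its activated homolog.
#'
#' @return Named character vector with elements \code{Ab} and
#'   \code{Ab2_hybrid}.
#' @export
ab_exon_hybrid_pair <- function() {
  ab <- .AB_EXON
  hyb <- sub("GCUAGCAAAC", "GCUAGGAAAC", ab, fixed = TRUE)
  c(Ab = ab, Ab2_hybrid = hyb)
}

#' Printed 3' splice site organization of U2AF-regulated tandem exon pairs
#'
#' The summary-table values for the eight duplicated homologous exon pairs
#' (gene, exon/isoform, direction of U2AF-mediated regulation, imported
#' SVM BP score, PPT length, AGEZ length). These are imported published
#' annotations used as inputs; none of the columns is computed by this
#' package (in particular the SVM BP scores are external predictions).
#'
#' @return Data frame with one row per exon.
#' @export
table1_architecture <- function() {
  data.frame(
    gene = c("FYN", "FYN", "TPM1", "TPM1", "TPM2", "TPM2", "U2AF1", "U2AF1",
             "CALU", "CALU", "ACOX1", "ACOX1", "MAPK14", "MAPK14",
             "P4HA1", "P4HA1"),
    exon = c("7a", "7b", "6a", "6b", "6a", "6b", "Ab", "3",
             "3a", "3b", "3a", "3b", "9a", "9b", "10a", "10b"),
    u2af_effect = c("repression", "activation", "activation", "repression",
                    "activation", "repression", "repression", "activation",
                    "repression", "activation", "activation", "repression",
                    "repression", "activation", "activation", "repression"),
    svm_bp_score = c(0.66, 1.01, 1.21, 1.21, 2.34, 1.75, NA, NA,
                     1.39, 1.29, 0.98, 1.31, 0.16, -0.47, 0.96, 1.03),
    ppt_length = c(43L, 11L, 6L, 67L, 16L, 106L, 25L, 9L,
                   27L, 12L, 19L, 10L, 32L, 8L, 7L, 22L),
    agez = c(61L, 35L, 104L, 88L, 34L, 131L, 31L, 21L,
             48L, 35L, 24L, 59L, 61L, 56L, 44L, 26L),
    stringsAsFactors = FALSE)
}

#' Small demonstration enhancer motif set
#'
#' A handful of purine-rich exonic splicing enhancer cores (including GAA)
#' for tests and examples. Published motif collections (FAS-ESS, PESE/PESS,
#' RESCUE-ESE, SR ESEs, EIEs) are user-supplied files; see [read_motifs()].
#'
#' @return A [motif_set()].
#' @export
demo_ese_motifs <- function() {
  motif_set("demo_ese", c("GAA", "GAAGAA", "AAGAAG", "GAGGAA"),
            polarity = "enhancer")
}
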