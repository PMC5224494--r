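---
title: "3' splice site architecture of repressed duplicated exons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3' splice site architecture of repressed duplicated exons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicearch)
```

## The problem

Tandem duplicated exons are usually spliced mutually exclusively, and in
several U2AF-regulated gene families one homolog is persistently repressed
even though its splice-site sequences look stronger on paper. The repressed
homolog of the *U2AF1* pair (exon Ab, encoding U2AF35b) sits downstream of
an unusual 3' splice site: a long pure polypyrimidine tract (PPT) directly
abutting a cluster of weak, closely spaced branch points (BPs), none of
which carries the canonical uridine two nucleotides upstream of the branch
adenine, inside a long AG exclusion zone (AGEZ), with an ultraconserved
stem loop (the ESL) a short distance further upstream. This package
implements, as reusable and tested code, the sequence-level analyses that
characterize such an architecture:

1. **AGEZ / PPT annotation** of a 3' splice site (`compute_agez`,
   `find_ppt`, `assemble_architecture`);
2. **U2 snRNA duplex scoring** of candidate branch points in the canonical
   and shifted base-pairing registers (`score_duplex`,
   `enumerate_registers`, `branch_candidates`);
3. **RNA accessibility** (probability-of-unpaired, PU) profiles from an
   exact partition function, with repressed-vs-activated group comparison
   (`pu_profile`, `compare_groups`);
4. **Hairpin (ESL) stability** for a mutation panel and its correlation
   with measured exon inclusion (`apply_mutation`, `fold_hairpin`,
   `stability_inclusion_correlation`);
5. **Lariat-read branch-point mapping** by mismatch-tolerant search for the
   intron 5'-end k-mer (`scan_reads`, `call_bp`, `aggregate_calls`);
6. **Splicing-motif density** over exons (`count_motifs`);
7. **Seeded synthetic data generators** with exact planted ground truth for
   every input class (`generate_locus`, `simulate_lariat_reads`,
   `simulate_inclusion`).

## Coordinates

All user-facing coordinates are signed and anchored at the 3' splice site:
position -1 is the last intron nucleotide (the G of the terminal AG), +1
the first exon nucleotide, and there is no position 0. "BP-31" is the
branch adenine 31 nt upstream of the intron/exon junction. Internally the
package stores 0-based offsets; `signed_to_internal` is the bijection
between the two.

## AGEZ and PPT

The AGEZ scan starts at -3 and walks 5'-ward for the nearest dinucleotide
AG (A at p, G at p+1); the reported length is |p| - 2, the number of
positions strictly between the upstream AG and the 3'ss AG. This is the
convention under which the exon Ab-like fixture reproduces the published
AGEZ of 31 with its nearest upstream AG at -33. If no AG occurs within
`max_scan` (default 200 nt) the zone is flagged open-ended.

Because the tool that produced the published PPT lengths is not itself
reproduced here, the default PPT definition is deliberately the simplest
reproducible one: the longest uninterrupted run of pyrimidines inside the
AGEZ, ties resolved toward the 3'-most run, minimum length 5
(`mode = "pure_run"`). An `interruption_tolerant` mode (maximal segment
under +1 per pyrimidine / -2 per purine, pyrimidine endpoints) is provided
for sensitivity analyses. Exact reproduction of PPT lengths that the
external SVM-based tool produced for other genes is therefore not promised.

## U2 duplex scoring and shifted registers

The U2 snRNA guide is stored 5'->3' as the branch-interacting box `GUAGUA`
(the "AUGAUG box" read 3'->5') flanked by the adjacent single-stranded U2
stretches `AUCAAGU` (5') and `UCUGUUC` (3'); all three parts and the
hydrogen-bond table (`G:C = 3`, `A:U = 2`, wobble `G:U = 2`) are
configuration, not constants, because the published figures do not print
the counting rules. In the canonical register the guide core pairs with the
five positions 5' of the bulged branch adenosine and one position 3' of it,
the geometry of the textbook UACUAAC/GUAGUA duplex (14 hydrogen bonds with
the branch A bulged; this value is a frozen test oracle). A register shift
of s slides the guide footprint s positions toward the intron 3' end
(positive) or 5' end (negative); exactly one nucleotide is bulged per
register, by default the branch adenosine (`bulge_policy = "any_adenosine"`
explores alternative bulged nucleophiles).

Two counts are reported per register. `hbonds_core` sums bonds over the
6-nt core footprint; mismatches contribute zero but do not truncate.
`hbonds_extended` adds the single-stranded guide flanks by **helix
propagation**: pairs accrue outward from each core edge only while
consecutive pairs keep forming, stopping at the first non-pairing position.
This choice is deliberate. Counting every coincidental pair across the full
reach of the flanks would credit biophysically meaningless isolated
contacts and makes canonical and shifted registers share most of their
score; a drawn duplex diagram counts its contiguous helix, and so does this
package. The best register maximizes `hbonds_extended`, with deterministic
tie-breaks: smaller absolute shift, then the more negative shift, then the
5'-most bulge.

Two caveats are worth stating. First, with wobble pairs in the bond table
the score is not invariant under reverse-complementing both strands (the
complement of G:U is the non-pairing C:A); the invariance holds exactly for
a wobble-free bond table, and the test suite asserts it in that form.
Second, the hydrogen-bond integers printed in the source figures are not
available in the running text, so they are not used as fixtures anywhere;
the scorer is validated against hand-derived examples, an independent
alignment-construction oracle, and brute-force register enumeration.

## PU profiles: the pair-count ensemble

The default accessibility model is a uniform pair-energy ("pair count")
ensemble: every admissible pair (Watson-Crick plus G:U unless
`allow_gu = FALSE`) contributes energy -epsilon (default 1, in kT units),
structures are nested with hairpin loops of at least 3 nt, and there is no
lonely-pair restriction. Inside/outside dynamic programming gives exact
pair probabilities P(i,j); PU(i) is computed by an independent
constrained-inside recursion with position i forbidden to pair, so the
identity `sum_j P(i,j) + PU(i) = 1` (asserted to 1e-12) is a genuine
cross-check between two recursions rather than a definition. Profiles for
sequences up to 20 nt are additionally checked against exhaustive structure
enumeration to 1e-9 over hundreds of random sequences.

This model was chosen over a full nearest-neighbor implementation because
it is self-contained and oracle-verifiable, and because the exact windowing
and energy settings behind the published PU tables are not printed in the
source; a nearest-neighbor backend can be plugged in via
`options(splicearch.nn_backend = )` without changing any contract. Two
numerical notes: the outside recursion for this homopolymer-energy model
has no multiloop factorization, so the implementation is O(n^4) in C++ and
the default length cap is 300 nt (double-precision partition functions
overflow near 450 nt at epsilon = 1); and as epsilon -> 0 the profile tends
to the unweighted combinatorial ensemble, *not* to PU = 1 (pairing remains
entropically available even when it is energetically neutral), while mean
PU decreases monotonically in epsilon.

Group comparisons pool position-specific PU values over a selected region
(for tandem-exon analyses: the intron upstream of the 3'ss, or the intron
downstream of the 5'ss) and use the two-sided Wilcoxon-Mann-Whitney test --
exact null for combined n <= 25 without ties, normal approximation with
continuity and tie correction otherwise. Reproducing the published mean PU
table for the eight real exon pairs requires hg19 genomic sequence and the
original method's unprinted windowing; that check is external and
non-gating, and no test asserts it.

## Hairpin stability and the inclusion correlation

`fold_hairpin` reports the minimum-energy nested structure under the same
pair-count model (energy -epsilon per pair), with a deterministic
traceback: the 5'-most position is paired with its smallest co-optimal
partner, yielding the 5'-most outermost pair among co-optimal structures.
The wild-type ESL is defined operationally as the reverse complement of the
printed RC replacement 25-mer, and the scrambled (SCR) replacement must
have the same base composition -- both facts are asserted in the tests. The
mutation panel encodes the published variant set (stabilizing C>G loop
substitutions, the 7-nt 5'-stem deletion, the stem G/C swap, loop
substitutions, SCR and RC) with reference-base verification at every edit,
so a coordinate bug fails loudly. Under the pair-count model the stated
directions hold: SCR and the stem deletion destabilize, the C>G
substitutions stabilize. Published kcal/mol values came from an external
nearest-neighbor folder and are figure-bound; this package reproduces
orderings and the correlation workflow, not those numbers.

`stability_inclusion_correlation` reports Pearson r with the two-sided
t-based p-value (plus Spearman's rho) between panel delta G and measured
inclusion. The synthetic inclusion generator treats the panel's delta G
values as a fixed design and adds logistic-link means plus Gaussian noise;
`calibrate_noise_sd` solves for the noise SD that yields a requested
population correlation under that fixed design. With the 11-variant panel
and target r = 0.8, the n = 11 workflow detects a positive association
(r > 0, p < 0.05) in about 97% of seeded replicates, and its type-I error
at zero association is within [0.03, 0.07] -- both measured, not assumed,
by the acceptance suite.

## Lariat-read branch-point mapping

A read spans the 2'-5' branch junction if it contains the intron 5'-end
k-mer (k = 15 or 20, Hamming distance <= 3 by default -- the published
string-search parameters) while its preceding bases do not continue the
upstream exon (the `exclude_prefix` filter removes ordinary unspliced
reads). The mismatch metric is Hamming throughout: the search being
reproduced is substitution-tolerant only, and indel alignment is out of
scope. Both orientations are scanned, reverse-strand hits carry a flag.
Branch calling matches the anchor (default 12 nt) immediately 5' of the
junction exactly against the intron except at the branch base itself, which
may read A or T -- reverse transcription across the 2'-5' bond produces the
diagnostic A>T misincorporation. Anchors matching at several intron
positions are reported ambiguous, never silently resolved. The scanner is
required, by the acceptance suite, to agree exactly with a brute-force
per-offset Hamming oracle on 10^4 simulated reads at both k values.

## Motif density

`count_motifs` counts occurrences at every start position (overlaps
included by default) and reports two normalizations side by side -- hits
per nucleotide and positional coverage -- because the normalization used by
the source's cited density calculation is not printed. Published motif
collections are user-supplied files; the package ships only a small
demonstration set of purine-rich enhancer cores (including GAA).

## The synthetic-data generators

`generate_locus` plants, in a documented layering order (background
composition, hairpin, PPT, purine caps, BP-2 bases, branch adenines, the
3'ss and AGEZ-defining AGs, then an AG scrub over the exclusion zone),
every feature the architecture stages measure, and returns the exact
planted truth. Feasibility is checked up front (tract capacity inside the
AGEZ, no competing pyrimidine run as long as the planted tract, branch
positions 5' of the tract, hairpin clear of the branch cluster), and
purine interruptions inside an impure PPT are drawn as adenines so no AG
can arise inside the tract. Generators are pure functions of
(recipe, seed); a single seed is fanned out to per-generator streams by
stable labels. What the generator does *not* emulate: real dinucleotide
composition, splice-site strength outside the planted features, expression
or NMD effects, and sequencing error profiles beyond uniform substitution
noise -- so a green synthetic test establishes algorithmic correctness on
known ground truth, not biological performance on real libraries.

## The exon Ab-like fixture

The source prints the sequence upstream of exon Ab only inside a figure
panel, which is not part of the extracted text this package was built from.
`u2af1_ab_synthetic_locus()` is therefore a frozen, clearly labelled
synthetic stand-in, designed once (by a seeded constraint search, then
hard-coded) to satisfy every architecture fact the running text and summary
table do state: AGEZ 31 with the nearest upstream AG at -33; a pure-run PPT
of 25 at -28..-4; four branch adenines within [-40, -30] including the
textually pinned -31 and -33 (the remaining two, -40 and -35, are design
choices); four AGs tiled through the branch cluster; no pyrimidine at any
BP-2; the ESL at -85..-61 equal to the reverse complement of the printed RC
25-mer; a GUAAGU 5' splice site; and best shifted-register hydrogen-bond
counts more than twice the canonical count at every branch point. Tests
running on this fixture validate the code paths against the stated values;
they do not certify the literal genomic sequence.

## Worked example

```{r example}
ab <- u2af1_ab_synthetic_locus()
compute_agez(ab)$agez_length
find_ppt(ab)$length
cands <- branch_candidates(ab, u2af1_ab_bp_positions())
data.frame(
  bp = vapply(cands, `[[`, integer(1), "pos"),
  consensus = vapply(cands, `[[`, character(1), "consensus"),
  canonical = vapply(cands, function(x) x$canonical_register$hbonds_extended,
                     numeric(1)),
  best_shifted = vapply(cands, function(x) x$best_register$hbonds_extended,
                        numeric(1)),
  shift = vapply(cands, function(x) x$best_register$shift, integer(1)))
```

## Known limitations

- The default energy model is pair-counting, not nearest-neighbor
  thermodynamics; delta G values are in model units and only orderings are
  claimed.
- Pseudoknots, co-transcriptional folding and protein binding are outside
  every model here.
- The lariat machinery processes read sets against a supplied intron; it is
  not a transcriptome aligner.
- Published SVM branch-point scores and maximum-entropy splice-site scores
  are imported annotations, never computed.
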