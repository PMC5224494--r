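ab <- u2af1_ab_synthetic_locus()
ab_intron <- chartr("U", "T", ab$intron_seq)

test_that("exact junction reads are detected at the planted offset", {
  kmer <- substr(ab_intron, 1, 20)
  seg <- substr(ab_intron, 70, 89)             # 20 nt ending at position -31
  read <- paste0(seg, kmer)
  hits <- scan_reads(c(r1 = read), kmer, max_mm = 3)
  plus <- hits[hits$orientation == "+", ]
  expect_identical(plus$match_offset, 21L)
  expect_identical(plus$mismatches, 0L)
})

test_that("four mismatches exceed the threshold", {
  kmer <- substr(ab_intron, 1, 20)
  mutk <- kmer
  for (i in c(2, 7, 12, 17)) {
    substr(mutk, i, i) <- setdiff(c("A", "C", "G", "T"),
                                  substr(kmer, i, i))[1]
  }
  read <- paste0(substr(ab_intron, 70, 89), mutk)
  hits <- scan_reads(c(r1 = read), kmer, max_mm = 3, both_strands = FALSE)
  expect_identical(nrow(hits), 0L)
})

test_that("reads continuing the upstream exon are excluded", {
  kmer <- substr(ab_intron, 1, 20)
  exon_end <- chartr("U", "T", substr(ab$upstream_exon_seq, 31, 50))
  pre_mrna_read <- paste0(exon_end, kmer)      # unspliced exon-intron read
  hits <- scan_reads(c(r1 = pre_mrna_read), kmer, max_mm = 3,
                     exclude_prefix = exon_end, both_strands = FALSE)
  expect_identical(nrow(hits), 0L)
  # the same junction with a lariat-style (intron) prefix is kept
  lariat_read <- paste0(substr(ab_intron, 70, 89), kmer)
  hits2 <- scan_reads(c(r1 = lariat_read), kmer, max_mm = 3,
                      exclude_prefix = exon_end, both_strands = FALSE)
  expect_identical(nrow(hits2), 1L)
})

test_that("reverse-orientation junctions are found and flagged", {
  kmer <- substr(ab_intron, 1, 20)
  read <- paste0(substr(ab_intron, 70, 89), kmer)
  rc_read <- reverse_complement(read)
  hits <- scan_reads(c(r1 = rc_read), kmer, max_mm = 3)
  expect_true(all(hits$orientation == "-"))
  expect_identical(nrow(hits[hits$orientation == "-", ]), 1L)
})

test_that("scan decisions equal the brute-force Hamming oracle", {
  set.seed(51)
  sim <- simulate_lariat_reads(
    ab, c(`-40` = 0.25, `-35` = 0.25, `-33` = 0.25, `-31` = 0.25),
    n_reads = 300L, read_len = 50L, k = 20L, sub_rate = 0.02,
    a_to_t_rate = 0.2, seed = 51L)
  hits <- scan_reads(sim$reads, sim$five_ss_kmer, max_mm = 3L,
                     both_strands = FALSE)
  for (id in names(sim$reads)) {
    got <- hits[hits$read_id == id, c("match_offset", "mismatches")]
    exp <- oracle_hamming_hits(sim$reads[[id]], sim$five_ss_kmer, 3L)
    expect_identical(unname(as.integer(got$match_offset)),
                     unname(as.integer(exp$offset)))
    expect_identical(unname(as.integer(got$mismatches)),
                     unname(as.integer(exp$mm)))
  }
})

test_that("call_bp recovers planted positions and the A>T diagnostic", {
  kmer <- substr(ab_intron, 1, 20)
  for (bp in u2af1_ab_bp_positions()) {
    bidx <- nchar(ab_intron) + bp + 1L
    seg <- substr(ab_intron, bidx - 19L, bidx)
    read <- list(seq = paste0(seg, kmer), match_offset = 21L)
    call <- call_bp(read, ab_intron)
    expect_false(call$ambiguous)
    expect_identical(call$bp_pos, bp)
    expect_identical(call$branch_base_observed, "A")
    # the diagnostic A>T at the branch base maps to the same position
    seg_t <- seg
    substr(seg_t, 20L, 20L) <- "T"
    call_t <- call_bp(list(seq = paste0(seg_t, kmer), match_offset = 21L),
                      ab_intron)
    expect_identical(call_t$bp_pos, bp)
    expect_identical(call_t$branch_base_observed, "T")
  }
})

test_that("repeated anchors are flagged ambiguous, never silently resolved", {
  rep_intron <- paste0("GTAAGT", strrep("TGCATGCTGCAA", 4), "TTTTTTAG")
  # a full 12-nt repeat unit ending in A occurs at four intron positions
  aidx <- 30L
  anchor <- substr(rep_intron, aidx - 11L, aidx)
  stopifnot(anchor == "TGCATGCTGCAA")
  read <- list(seq = paste0(anchor, substr(rep_intron, 1, 20)),
               match_offset = 13L)
  call <- call_bp(read, rep_intron)
  expect_true(call$ambiguous)
  expect_true(is.na(call$bp_pos))
  expect_gt(length(call$candidates), 1L)
})

test_that("call_bp refuses short anchors and absent anchors", {
  kmer <- substr(ab_intron, 1, 20)
  expect_error(call_bp(list(seq = paste0("ACGT", kmer), match_offset = 5L),
                       ab_intron), "min_anchor")
  expect_error(call_bp(list(seq = paste0("ACGTACGTACGTACGA", kmer),
                            match_offset = 17L), ab_intron), "not found")
})

test_that("aggregate_calls groups, sorts and normalizes usage", {
  mk <- function(pos, base = "A") structure(
    list(bp_pos = pos, ambiguous = FALSE, branch_base_observed = base),
    class = "branch_point_call")
  calls <- c(lapply(c(-31L, -31L, -33L, -40L), mk), list(mk(-35L, "T")))
  tab <- aggregate_calls(calls)
  expect_identical(tab$bp_pos, c(-40L, -35L, -33L, -31L))
  expect_identical(tab$support, c(1L, 1L, 1L, 2L))
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-12)
  expect_identical(tab$n_t[tab$bp_pos == -35], 1L)
  # single call and empty input edge cases
  one <- aggregate_calls(list(mk(-31)))
  expect_identical(one$fraction, 1)
  empty <- aggregate_calls(list())
  expect_identical(nrow(empty), 0L)
})

test_that("the pipeline recovers planted usage fractions within binomial error", {
  usage <- c(`-40` = 0.10, `-35` = 0.20, `-33` = 0.30, `-31` = 0.40)
  sim <- simulate_lariat_reads(ab, usage, n_reads = 2000L, read_len = 50L,
                               k = 20L, sub_rate = 0, a_to_t_rate = 0.25,
                               seed = 7L)
  res <- lariat_pipeline(sim$reads, ab$intron_seq, k = 20L)
  expect_identical(res$usage$bp_pos, as.integer(names(usage)[order(as.integer(names(usage)))]))
  for (p in names(usage)) {
    got <- res$usage$fraction[res$usage$bp_pos == as.integer(p)]
    ci <- 1.96 * sqrt(usage[[p]] * (1 - usage[[p]]) / 2000)
    expect_lt(abs(got - usage[[p]]), ci + 0.01)
  }
  # per-read recovery is exact at zero substitution noise
  calls_pos <- vapply(res$calls, `[[`, integer(1), "bp_pos")
  expect_identical(sort(unique(calls_pos)), sort(unique(sim$truth$bp_pos)))
})
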