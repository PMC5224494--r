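test_that("apply_mutation performs verified substitutions, deletions, swaps", {
  wt <- wt_esl()
  panel <- esl_mutation_panel()
  expect_identical(apply_mutation(wt, panel$WT), wt)               # identity
  g68 <- apply_mutation(wt, panel[["G-68"]])
  expect_identical(substr(g68, 18, 18), "G")
  expect_identical(substr(wt, 18, 18), "C")
  expect_identical(apply_mutation(wt, panel$RC), esl_rc_25mer())
  expect_identical(apply_mutation(wt, panel$SCR), esl_scr_25mer())
  del <- apply_mutation(wt, panel[["del-79-85"]])
  expect_identical(nchar(del), 18L)
  expect_identical(del, substr(wt, 8, 25))
  # ref mismatch is refused with the position named
  bad <- mutation_spec("bad", subs = data.frame(pos = -68, ref = "A", alt = "G"))
  expect_error(apply_mutation(wt, bad), "-68")
})

test_that("applying the inverse edit restores the wild type", {
  wt <- wt_esl()
  fwd <- mutation_spec("f", subs = data.frame(pos = c(-78, -68),
                                              ref = c("C", "C"),
                                              alt = c("G", "A")))
  mut <- apply_mutation(wt, fwd)
  inv <- mutation_spec("i", subs = data.frame(pos = c(-78, -68),
                                              ref = c("G", "A"),
                                              alt = c("C", "C")))
  expect_identical(apply_mutation(mut, inv), wt)
})

test_that("a perfect inverted repeat folds into its full stem", {
  stem <- "GCGCGCGC"
  hp <- paste0(stem, "AAAA", reverse_complement(stem))
  ev <- fold_hairpin(hp)
  expect_identical(ev$n_pairs, 8L)
  expect_identical(ev$delta_g, -8)
  expect_identical(ev$structure, "((((((((....))))))))")
})

test_that("fold_hairpin maximizes pairs (enumeration oracle) deterministically", {
  set.seed(41)
  for (i in 1:30) {
    s <- random_rna(sample(10:16, 1))
    ev <- fold_hairpin(s)
    expect_identical(ev$n_pairs, as.integer(oracle_max_pairs(s)))
    expect_identical(fold_hairpin(s)$structure, ev$structure)
    # dot-bracket is balanced and consistent with the pair count
    db <- strsplit(ev$structure, "")[[1]]
    expect_identical(sum(db == "("), sum(db == ")"))
    expect_identical(sum(db == "("), ev$n_pairs)
  }
})

test_that("reverse complement preserves energy when pairs survive complementation", {
  # Watson-Crick-only admissibility is closed under complementation, so the
  # minimum energy is exactly RC-invariant for every sequence; with G:U
  # wobbles admitted the invariance holds for the pairing graphs that map
  # onto themselves (perfect WC inverted repeats folding to the full stem)
  set.seed(42)
  for (i in 1:20) {
    x <- random_rna(sample(12:30, 1))
    expect_identical(fold_hairpin(x, allow_gu = FALSE)$delta_g,
                     fold_hairpin(reverse_complement(x), allow_gu = FALSE)$delta_g)
  }
  hp <- paste0("GCAUGCGC", "AAAA", reverse_complement("GCAUGCGC"))
  expect_identical(fold_hairpin(hp)$n_pairs, 8L)
  expect_identical(fold_hairpin(hp)$delta_g,
                   fold_hairpin(reverse_complement(hp))$delta_g)
})

test_that("Watson-Crick repair of a mismatched stem never destabilizes", {
  # stem with a planted internal mismatch; mutating it to the WC partner
  # of its opposite base must not raise delta G
  hp0 <- paste0("GCGAGCGC", "AAAA", "GCGCCCGC")  # A..C mismatch at 4/13
  ev0 <- fold_hairpin(hp0)
  hp1 <- paste0("GCGGGCGC", "AAAA", "GCGCCCGC")  # G:C restored
  ev1 <- fold_hairpin(hp1)
  expect_lte(ev1$delta_g, ev0$delta_g)
})

test_that("the ESL panel reproduces the stated stability orderings", {
  evals <- fold_panel(wt_esl(), esl_mutation_panel())
  dg <- vapply(evals, `[[`, numeric(1), "delta_g")
  expect_gt(dg[["SCR"]], dg[["WT"]])          # scramble destabilizes
  expect_gt(dg[["del-79-85"]], dg[["WT"]])    # 5' stem deletion destabilizes
  expect_lte(dg[["G-68"]], dg[["WT"]])        # loop C>G stabilizes
  expect_lte(dg[["G-78"]], dg[["WT"]])
  expect_lte(dg[["G-76_G-68"]], dg[["G-68"]]) # hyperstabilization
  # RC and the G/C stem swap stay within one wobble pair of the wild type
  # (exact equality holds only for wobble-free pairing graphs)
  expect_lte(abs(dg[["RC"]] - dg[["WT"]]), 1)
  expect_lte(abs(dg[["swap-63-64"]] - dg[["WT"]]), 1)
})

test_that("stability_inclusion_correlation recovers exact and noisy signals", {
  evals <- fold_panel(wt_esl(), esl_mutation_panel())
  dg <- vapply(evals, `[[`, numeric(1), "delta_g")
  # perfectly linear synthetic inclusion -> r = 1
  inc <- data.frame(variant_id = names(dg), inclusion_pct = 50 + 3 * dg)
  res <- stability_inclusion_correlation(evals, inc)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_identical(res$n, length(dg))
  # agreement with the direct-formula oracle on random pairs
  set.seed(43)
  x <- rnorm(10); y <- rnorm(10)
  ev10 <- lapply(1:10, function(i) {
    structure(list(variant_id = paste0("v", i), delta_g = x[i]),
              class = "hairpin_evaluation")
  })
  inc10 <- data.frame(variant_id = paste0("v", 1:10), inclusion_pct = y)
  got <- stability_inclusion_correlation(ev10, inc10)
  exp <- oracle_pearson(x, y)
  expect_equal(got$r, exp$r, tolerance = 1e-12)
  expect_equal(got$p, exp$p, tolerance = 1e-12)
  # unmatched ids and zero variance are refused
  expect_error(stability_inclusion_correlation(ev10, inc10[1:5, ]), "unmatched")
  flat <- lapply(1:5, function(i) structure(
    list(variant_id = paste0("v", i), delta_g = 1), class = "hairpin_evaluation"))
  expect_error(
    stability_inclusion_correlation(flat,
      data.frame(variant_id = paste0("v", 1:5), inclusion_pct = rnorm(5))),
    "variance")
})
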