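test_that("generate_locus plants exactly the recipe's architecture", {
  set.seed(81)
  for (seed in c(1L, 7L, 99L)) {
    rec <- locus_recipe(seed = seed)
    gen <- generate_locus(rec)
    ag <- compute_agez(gen$locus)
    expect_identical(ag$agez_length, gen$truth$agez_length)
    expect_identical(ag$first_upstream_ag_pos, gen$truth$first_upstream_ag_pos)
    ppt <- find_ppt(gen$locus)
    expect_identical(ppt$length, gen$truth$ppt_len)
    expect_identical(c(ppt$start, ppt$end), gen$truth$ppt_interval)
    expect_identical(ppt$pyrimidine_fraction, 1)
    for (bp in gen$truth$bp_positions) {
      expect_identical(base_at(bp, gen$locus), "A")
      expect_false(is_pyr <- base_at(bp - 2L, gen$locus) %in% c("C", "U"))
    }
    # hairpin arms are exact reverse complements
    hp <- gen$truth$hairpin_interval
    sl <- rec$hairpin$stem_len
    arm5 <- site_region_seq(gen$locus, hp[1], hp[1] + sl - 1L)
    arm3 <- site_region_seq(gen$locus, hp[2] - sl + 1L, hp[2])
    expect_identical(arm3, reverse_complement(arm5, "RNA"))
  }
})

test_that("generation is a pure function of (recipe, seed)", {
  g1 <- generate_locus(locus_recipe(seed = 5L))
  g2 <- generate_locus(locus_recipe(seed = 5L))
  g3 <- generate_locus(locus_recipe(seed = 6L))
  expect_identical(g1$locus$intron_seq, g2$locus$intron_seq)
  expect_false(identical(g1$locus$intron_seq, g3$locus$intron_seq))
  expect_identical(g1$truth, g3$truth)   # planted metrics identical
})

test_that("ppt_purity below 1 plants adenine interruptions, purity 1 none", {
  gen <- generate_locus(locus_recipe(ppt_purity = 0.8, seed = 3L))
  ppt_seq <- site_region_seq(gen$locus, gen$truth$ppt_interval[1],
                             gen$truth$ppt_interval[2])
  ch <- strsplit(ppt_seq, "")[[1]]
  expect_identical(sum(!ch %in% c("C", "U")), 5L)   # round(0.2 * 25)
  expect_true(all(ch[!ch %in% c("C", "U")] == "A"))
  expect_equal(gen$truth$ppt_pyr_fraction, 0.8, tolerance = 1e-12)
  # pure-run annotation in tolerant mode still spans the tract
  ppt <- find_ppt(gen$locus, mode = "interruption_tolerant")
  expect_gte(ppt$length, 5L)
})

test_that("infeasible recipes are rejected up front", {
  expect_error(locus_recipe(ppt_len = 29L, agez_target = 31L), "infeasible")
  expect_error(locus_recipe(ppt_len = 10L, agez_target = 31L), "infeasible")
  expect_error(locus_recipe(bp_positions = c(-20L)), "infeasible")
  expect_error(locus_recipe(intron_len = 35L), "infeasible")
  expect_error(locus_recipe(hairpin = list(stem_len = 9L, loop_len = 7L,
                                           offset = -45L)), "infeasible")
})

test_that("an exon Ab-like recipe reproduces the table architecture", {
  rec <- locus_recipe(agez_target = 31L, ppt_len = 25L,
                      bp_positions = c(-40L, -35L, -33L, -31L), seed = 17L)
  gen <- generate_locus(rec)
  expect_identical(compute_agez(gen$locus)$agez_length, 31L)
  expect_identical(find_ppt(gen$locus)$length, 25L)
  cands <- branch_candidates(gen$locus, rec$bp_positions)
  expect_true(all(vapply(cands, `[[`, character(1), "consensus") ==
                    "noncanonical"))
})

test_that("simulated lariat reads honor their noise parameters", {
  ab <- u2af1_ab_synthetic_locus()
  # zero noise, one BP: every read is called at that BP
  sim <- simulate_lariat_reads(ab, c(`-33` = 1), n_reads = 100L,
                               read_len = 50L, k = 20L, sub_rate = 0,
                               a_to_t_rate = 0, seed = 2L)
  res <- lariat_pipeline(sim$reads, ab$intron_seq, k = 20L)
  expect_identical(res$usage$bp_pos, -33L)
  expect_identical(res$usage$support, 100L)
  # a_to_t_rate 1: all branch bases read T, positions unchanged
  simT <- simulate_lariat_reads(ab, c(`-33` = 1), n_reads = 50L,
                                read_len = 50L, k = 20L, sub_rate = 0,
                                a_to_t_rate = 1, seed = 2L)
  resT <- lariat_pipeline(simT$reads, ab$intron_seq, k = 20L)
  expect_identical(resT$usage$bp_pos, -33L)
  expect_identical(resT$usage$n_t, 50L)
  expect_identical(resT$usage$n_a, 0L)
  # determinism and fraction validation
  sim2 <- simulate_lariat_reads(ab, c(`-33` = 1), n_reads = 50L,
                                read_len = 50L, k = 20L, sub_rate = 0,
                                a_to_t_rate = 1, seed = 2L)
  expect_identical(simT$reads, sim2$reads)
  expect_error(simulate_lariat_reads(ab, c(`-33` = 0.5), 10L), "sum to 1")
  expect_error(simulate_lariat_reads(ab, c(`-33` = 1), 10L, read_len = 20L,
                                     k = 20L), "too short")
})

test_that("simulate_inclusion is deterministic, clamped and noise-faithful", {
  dg <- c(v1 = -9, v2 = -7, v3 = -5, v4 = -10, v5 = -8)
  m0 <- inclusion_model(intercept = 0.2, coef_dg = 0.1, noise_sd = 0)
  t1 <- simulate_inclusion(dg, m0, seed = 4L)
  t2 <- simulate_inclusion(dg, m0, seed = 4L)
  expect_identical(t1, t2)
  mu <- 100 * stats::plogis(0.2 + 0.1 * dg)
  expect_equal(t1$inclusion_pct, unname(mu), tolerance = 1e-12)
  expect_true(all(t1$inclusion_pct >= 0 & t1$inclusion_pct <= 100))
  # zero noise, positive slope -> r exactly 1 through the workflow
  evs <- lapply(names(dg), function(v) structure(
    list(variant_id = v, delta_g = dg[[v]]), class = "hairpin_evaluation"))
  res <- stability_inclusion_correlation(evs, t1)
  expect_gt(res$r, 0.99)
})

test_that("calibrate_noise_sd hits the requested population correlation", {
  dg <- c(-11, -10, -10, -9, -9, -8, -8, -7, -7, -6, -5)
  names(dg) <- paste0("v", seq_along(dg))
  model <- inclusion_model(intercept = 0, coef_dg = 0.08)
  sd_cal <- calibrate_noise_sd(dg, model, target_r = 0.8)
  model$noise_sd <- sd_cal
  # empirical correlation over many replicates concentrates near 0.8
  set.seed(85)
  rs <- vapply(1:400, function(i) {
    inc <- simulate_inclusion(dg, model, seed = i)
    stats::cor(dg, inc$inclusion_pct)
  }, numeric(1))
  expect_gt(mean(rs), 0.72)
  expect_lt(mean(rs), 0.88)
})
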