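#' Run code with a temporary RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a per-stream 32-bit seed from a base seed and a stable label
stream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 7919L + h * 104729L) %% 2147483545L + 1L
}

#' Recipe for a synthetic intron-exon locus with planted architecture
#'
#' The generator plants, in a documented layering order (background, hairpin,
#' PPT, AGEZ-defining AG, branch adenines, BP-2 bases, AGEZ scrub), every
#' feature the architecture stages measure, and returns exact ground truth.
#' Defaults emulate the architecture of a U2AF-repressed tandem exon: a long
#' pure polypyrimidine tract directly abutting a cluster of weak branch
#' points inside a long AGEZ, an optional upstream hairpin, and a 67-nt exon.
#'
#' @param intron_len Intron length (>= agez_target + 10).
#' @param agez_target Planted AGEZ length (the nearest upstream AG gets its A
#'   at \code{-(agez_target + 2)}).
#' @param ppt_len Planted PPT length; 3'-aligned at positions
#'   \code{-(ppt_len + 3)..-4} and capped by purines. Must satisfy
#'   \code{ppt_len <= agez_target - 3} and
#'   \code{agez_target - 3 - ppt_len < ppt_len} (so no competing run can tie).
#' @param ppt_purity Pyrimidine fraction of the tract (purine interruptions
#'   are adenines, so no AG can arise inside the tract).
#' @param bp_positions Signed branch adenine positions, all 5' of the PPT cap.
#' @param bp_minus2_base Base planted 2 nt 5' of each branch adenine
#'   (default "A": a noncanonical, pyrimidine-lacking BP-2).
#' @param hairpin \code{NULL} or \code{list(stem_len, loop_len, offset)} with
#'   \code{offset} the signed position of the hairpin's 5'-most base.
#' @param exon_len,flank_len Exon and outer-context lengths.
#' @param seed Integer seed; the generator is a pure function of
#'   (recipe, seed).
#' @return A \code{locus_recipe}.
#' @export
locus_recipe <- function(intron_len = 120L, agez_target = 31L, ppt_len = 25L,
                         ppt_purity = 1.0,
                         bp_positions = c(-38L, -36L, -33L, -31L),
                         bp_minus2_base = "A",
                         hairpin = list(stem_len = 9L, loop_len = 7L,
                                        offset = -85L),
                         exon_len = 67L, flank_len = 50L, seed = 1L) {
  r <- list(intron_len = as.integer(intron_len),
            agez_target = as.integer(agez_target),
            ppt_len = as.integer(ppt_len), ppt_purity = ppt_purity,
            bp_positions = sort(as.integer(bp_positions)),
            bp_minus2_base = toupper(bp_minus2_base),
            hairpin = hairpin, exon_len = as.integer(exon_len),
            flank_len = as.integer(flank_len), seed = as.integer(seed))
  if (r$ppt_len > r$agez_target - 3L) {
    stop("infeasible recipe: ppt_len must be <= agez_target - 3")
  }
  if (r$agez_target - 3L - r$ppt_len >= r$ppt_len) {
    stop("infeasible recipe: AGEZ gap could host a run as long as the PPT")
  }
  if (r$intron_len < r$agez_target + 10L) {
    stop("infeasible recipe: intron too short for the planted AGEZ")
  }
  ppt_cap <- -(r$ppt_len + 4L)
  if (any(r$bp_positions > ppt_cap)) {
    stop("infeasible recipe: branch positions must lie 5' of the PPT cap")
  }
  if (any(r$bp_positions == -(r$agez_target + 1L))) {
    stop("infeasible recipe: a branch position coincides with the planted AG's G")
  }
  if (any(r$bp_positions - 2L < -r$intron_len)) {
    stop("infeasible recipe: branch context outside the intron")
  }
  if (!is.null(r$hairpin)) {
    h <- r$hairpin
    hp_end <- h$offset + 2L * h$stem_len + h$loop_len - 1L
    if (h$offset < -r$intron_len || hp_end > -1L) {
      stop("infeasible recipe: hairpin outside the intron")
    }
    if (hp_end >= min(r$bp_positions) - 2L) {
      stop("infeasible recipe: hairpin overlaps the branch cluster")
    }
  }
  structure(r, class = "locus_recipe")
}

#' Generate a synthetic splice locus with exact planted ground truth
#'
#' @param recipe A [locus_recipe()].
#' @return List with \code{locus} (a [splice_locus()]) and \code{truth}
#'   (planted AGEZ, first AG position, PPT interval and realized purity,
#'   branch positions, hairpin interval).
#' @export
generate_locus <- function(recipe) {
  stopifnot(inherits(recipe, "locus_recipe"))
  r <- recipe
  with_seed(stream_seed(r$seed, "locus"), {
    L <- r$intron_len
    bases <- c("A", "C", "G", "U")
    chars <- sample(bases, L, replace = TRUE)
    idx <- function(pos) L + as.integer(pos) + 1L   # signed -> 1-based index
    protected <- integer(0)

    # hairpin: stem + loop + revcomp(stem)
    hp_interval <- NULL
    if (!is.null(r$hairpin)) {
      h <- r$hairpin
      stem <- sample(bases, h$stem_len, replace = TRUE)
      loop <- sample(bases, h$loop_len, replace = TRUE)
      rcst <- seq_chars(reverse_complement(paste(stem, collapse = "")))
      hp <- c(stem, loop, rcst)
      i0 <- idx(h$offset)
      chars[i0:(i0 + length(hp) - 1L)] <- hp
      hp_interval <- c(h$offset, h$offset + length(hp) - 1L)
    }

    # PPT, 3'-aligned at -4, purine interruptions drawn as A
    ppt_pos <- seq.int(-(r$ppt_len + 3L), -4L)
    n_pur <- round((1 - r$ppt_purity) * r$ppt_len)
    pur_at <- if (n_pur > 0) sample(seq_along(ppt_pos), n_pur) else integer(0)
    ppt_chars <- sample(c("C", "U"), r$ppt_len, replace = TRUE)
    ppt_chars[pur_at] <- "A"
    chars[idx(ppt_pos)] <- ppt_chars
    protected <- c(protected, idx(ppt_pos))

    # purine caps so the planted run is exactly the longest
    chars[idx(-3L)] <- "A"
    chars[idx(-(r$ppt_len + 4L))] <- "A"
    protected <- c(protected, idx(-3L), idx(-(r$ppt_len + 4L)))

    # branch -2 context, then branch adenines, then the AGs; later layers win
    chars[idx(r$bp_positions - 2L)] <- r$bp_minus2_base
    chars[idx(r$bp_positions)] <- "A"
    chars[idx(-2L)] <- "A"; chars[idx(-1L)] <- "G"
    chars[idx(-(r$agez_target + 2L))] <- "A"
    chars[idx(-(r$agez_target + 1L))] <- "G"
    protected <- c(protected, idx(r$bp_positions), idx(r$bp_positions - 2L),
                   idx(c(-2L, -1L)),
                   idx(-(r$agez_target + 2L)), idx(-(r$agez_target + 1L)))

    # scrub any accidental AG inside the exclusion zone
    for (p in seq.int(-(r$agez_target + 1L), -3L)) {
      i <- idx(p)
      if (chars[i] == "A" && chars[i + 1L] == "G") {
        if (!(i + 1L) %in% protected) {
          chars[i + 1L] <- "C"
        } else if (!i %in% protected) {
          chars[i] <- "C"
        } else {
          stop("infeasible recipe: planted features force an AG inside the AGEZ")
        }
      }
    }

    intron <- paste(chars, collapse = "")
    exon <- paste(sample(bases, r$exon_len, replace = TRUE), collapse = "")
    up_ex <- paste(sample(bases, r$flank_len, replace = TRUE), collapse = "")
    dn_in <- paste0("GUAAGU",
                    paste(sample(bases, max(0L, r$flank_len - 6L),
                                 replace = TRUE), collapse = ""))
    locus <- splice_locus(sprintf("synthetic_seed%d", r$seed), intron, exon,
                          upstream_exon_seq = up_ex,
                          downstream_intron_seq = dn_in)
    ppt_sel <- seq_chars(intron)[idx(ppt_pos)]
    list(locus = locus,
         truth = list(agez_length = r$agez_target,
                      first_upstream_ag_pos = -(r$agez_target + 2L),
                      ppt_interval = c(min(ppt_pos), max(ppt_pos)),
                      ppt_len = r$ppt_len,
                      ppt_pyr_fraction = mean(is_pyrimidine(ppt_sel)),
                      bp_positions = r$bp_positions,
                      hairpin_interval = hp_interval))
  })
}

#' Simulate lariat-junction-spanning reads with known ground truth
#'
#' Each read is (intron segment ending at a sampled branch adenine) followed
#' by (the intron 5'-end k-mer): the sequence a reverse transcriptase
#' produces reading through the 2'-5' branch junction. Substitution noise is
#' Bernoulli per base; the branch base itself is additionally flipped A->T
#' with probability \code{a_to_t_rate} (the diagnostic misincorporation at
#' the branched adenosine).
#'
#' @param locus A [splice_locus()] (its intron supplies both read parts).
#' @param bp_usage Named numeric vector mapping signed branch positions to
#'   usage fractions (must sum to 1).
#' @param n_reads Number of reads.
#' @param read_len Read length; the 5'ss k-mer occupies the last \code{k}
#'   bases, the branch-anchoring segment the first \code{read_len - k}.
#' @param k 5'ss k-mer length (15 or 20 typical).
#' @param sub_rate Per-base substitution probability.
#' @param a_to_t_rate Branch-base A->T probability.
#' @param seed Integer seed.
#' @return List with \code{reads} (named DNA character vector), \code{truth}
#'   (per-read planted position and branch base), \code{five_ss_kmer},
#'   \code{k}.
#' @export
simulate_lariat_reads <- function(locus, bp_usage, n_reads = 1000L,
                                  read_len = 60L, k = 20L, sub_rate = 0.01,
                                  a_to_t_rate = 0.2, seed = 1L) {
  stopifnot(inherits(locus, "splice_locus"))
  if (abs(sum(bp_usage) - 1) > 1e-9) stop("bp_usage fractions must sum to 1")
  intron <- chartr("U", "T", locus$intron_seq)
  n <- nchar(intron)
  m <- read_len - k
  if (m < 1L) stop("read_len too short to span the junction")
  pos <- as.integer(names(bp_usage))
  if (any(n + pos + 1L - m + 1L < 1L)) {
    stop("read_len too long: anchor segment would run past the intron start")
  }
  with_seed(stream_seed(seed, "lariat_reads"), {
    kmer <- substr(intron, 1L, k)
    draw <- sample(pos, n_reads, replace = TRUE, prob = bp_usage)
    bases <- c("A", "C", "G", "T")
    reads <- character(n_reads)
    branch_obs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      bidx <- n + draw[i] + 1L
      seg <- substr(intron, bidx - m + 1L, bidx)
      read <- paste0(seg, kmer)
      rc <- seq_chars(read)
      sub <- which(stats::runif(read_len) < sub_rate)
      for (s in sub) rc[s] <- sample(setdiff(bases, rc[s]), 1L)
      if (stats::runif(1) < a_to_t_rate) rc[m] <- "T"
      branch_obs[i] <- rc[m]
      reads[i] <- paste(rc, collapse = "")
    }
    names(reads) <- sprintf("read%05d", seq_len(n_reads))
    list(reads = reads,
         truth = data.frame(read_id = names(reads), bp_pos = draw,
                            branch_base = branch_obs,
                            stringsAsFactors = FALSE),
         five_ss_kmer = kmer, k = k)
  })
}

#' Inclusion-level noise model
#'
#' Exon inclusion (%) is generated as
#' \code{100 * plogis(intercept + coef_dg * dG + coef_ppt * ppt + coef_hbond
#' * hbonds) + N(0, noise_sd)}, clamped to [0, 100].
#'
#' @param intercept,coef_dg,coef_ppt,coef_hbond Linear predictor terms.
#' @param noise_sd Gaussian noise standard deviation (percentage points).
#' @return An \code{inclusion_model}.
#' @export
inclusion_model <- function(intercept = 0, coef_dg = 0, coef_ppt = 0,
                            coef_hbond = 0, noise_sd = 5) {
  structure(list(intercept = intercept, coef_dg = coef_dg,
                 coef_ppt = coef_ppt, coef_hbond = coef_hbond,
                 noise_sd = noise_sd, link = "logistic"),
            class = "inclusion_model")
}

#' Choose the noise SD that yields a target population correlation
#'
#' For a fixed design (the panel's delta G values are constants across
#' replicates) the population Pearson correlation between delta G and
#' generated inclusion is \code{cor(dg, mu) * sd(mu) / sqrt(sd(mu)^2 +
#' sigma^2)} where \code{mu} is the noiseless link mean; this solves for
#' \code{sigma}.
#'
#' @param dg Numeric vector of panel delta G values.
#' @param model An [inclusion_model()] (its \code{noise_sd} is ignored).
#' @param target_r Target correlation magnitude in (0, 1).
#' @return Noise SD in percentage points.
#' @export
calibrate_noise_sd <- function(dg, model, target_r = 0.8) {
  mu <- .inclusion_mean(dg, 0, 0, model)
  s <- stats::sd(mu) * sqrt(length(mu) - 1) / sqrt(length(mu))  # population sd
  s * sqrt(1 / target_r^2 - 1)
}

.inclusion_mean <- function(dg, ppt, hbond, model) {
  100 * stats::plogis(model$intercept + model$coef_dg * dg +
                      model$coef_ppt * ppt + model$coef_hbond * hbond)
}

#' Simulate an inclusion table for a variant panel
#'
#' @param dg Named numeric vector of delta G values (names are variant ids),
#'   or a list of \code{hairpin_evaluation}s.
#' @param model An [inclusion_model()].
#' @param seed Integer seed.
#' @param ppt,hbond Optional architecture covariates (recycled).
#' @return Data frame: \code{variant_id}, \code{inclusion_pct}.
#' @export
simulate_inclusion <- function(dg, model = inclusion_model(), seed = 1L,
                               ppt = 0, hbond = 0) {
  if (is.list(dg) && all(vapply(dg, inherits, logical(1), "hairpin_evaluation"))) {
    dg <- stats::setNames(vapply(dg, `[[`, numeric(1), "delta_g"),
                          vapply(dg, `[[`, character(1), "variant_id"))
  }
  stopifnot(is.numeric(dg), !is.null(names(dg)))
  with_seed(stream_seed(seed, "inclusion"), {
    mu <- .inclusion_mean(dg, ppt, hbond, model)
    pct <- mu + stats::rnorm(length(dg), 0, model$noise_sd)
    data.frame(variant_id = names(dg),
               inclusion_pct = pmin(100, pmax(0, pct)),
               stringsAsFactors = FALSE)
  })
}
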