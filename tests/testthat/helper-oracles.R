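# Independent brute-force oracles. These deliberately avoid the package's
# own algorithms: enumeration, direct formulas, and naive scans only.

oracle_chars <- function(seq) strsplit(toupper(seq), "", fixed = TRUE)[[1]]

.oracle_adm <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# every nested structure of seq (list of 2-col pair matrices), min-loop 3
oracle_structures <- function(seq, min_loop = 3L) {
  ch <- oracle_chars(seq)
  memo <- new.env(parent = emptyenv())
  enum <- function(i, j) {
    if (i > j) return(list(integer(0)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- enum(i + 1L, j)                       # i unpaired
    for (k in seq.int(i + min_loop + 1L, j)) {
      if (k > j) break
      if (!.oracle_adm(ch[i], ch[k])) next
      left <- enum(i + 1L, k - 1L)
      right <- enum(k + 1L, j)
      for (L in left) for (R in right) {
        out[[length(out) + 1L]] <- c(L, i, k, R)  # flat pair list
      }
    }
    memo[[key]] <- out
    out
  }
  if (min_loop + 2L > nchar(seq)) return(list(integer(0)))
  enum(1L, nchar(seq))
}

# exact PU by structure enumeration with Boltzmann weight exp(eps)^n_pairs
oracle_pu <- function(seq, eps = 1.0, min_loop = 3L) {
  n <- nchar(seq)
  structs <- oracle_structures(seq, min_loop)
  w <- vapply(structs, function(s) exp(eps * length(s) / 2), numeric(1))
  unpaired <- vapply(structs, function(s) {
    u <- rep(1, n); if (length(s)) u[s] <- 0; u
  }, numeric(n))
  if (n == 1L) unpaired <- matrix(unpaired, nrow = 1)
  as.numeric(unpaired %*% w) / sum(w)
}

oracle_max_pairs <- function(seq, min_loop = 3L) {
  max(vapply(oracle_structures(seq, min_loop), length, integer(1))) / 2
}

# brute-force AGEZ: scan every dinucleotide from -3 downward
oracle_agez <- function(intron, max_scan = 200L) {
  ch <- oracle_chars(intron)
  n <- length(ch)
  max_scan <- min(max_scan, n)
  for (p in -3L:(-(max_scan - 1L))) {
    i <- n + p + 1L
    if (i < 2L) break
    if (ch[i] == "A" && ch[i + 1L] == "G") {
      return(list(agez = -p - 2L, ag_at = p))
    }
  }
  list(agez = max_scan - 2L, ag_at = NA_integer_)
}

# all pyrimidine runs within signed interval [lo, hi] of an intron
oracle_pyr_runs <- function(intron, lo, hi) {
  ch <- oracle_chars(intron)
  n <- length(ch)
  pos <- seq.int(lo, hi)
  pyr <- ch[n + pos + 1L] %in% c("C", "U", "T")
  runs <- list()
  i <- 1L
  while (i <= length(pyr)) {
    if (pyr[i]) {
      j <- i
      while (j < length(pyr) && pyr[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(start = pos[i], end = pos[j],
                                     len = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

# naive per-offset Hamming scan over a read
oracle_hamming_hits <- function(read, kmer, max_mm) {
  rc <- oracle_chars(read); kc <- oracle_chars(kmer)
  k <- length(kc)
  hits <- data.frame(offset = integer(0), mm = integer(0))
  for (o in seq_len(length(rc) - k + 1L)) {
    d <- sum(rc[o:(o + k - 1L)] != kc)
    if (d <= max_mm) hits <- rbind(hits, data.frame(offset = o, mm = d))
  }
  hits
}

# exact Mann-Whitney p by full enumeration of group labelings
oracle_wilcoxon_exact <- function(a, b) {
  x <- c(a, b)
  na <- length(a)
  U_of <- function(idx) {
    aa <- x[idx]; bb <- x[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  obs <- U_of(seq_len(na))
  combs <- utils::combn(length(x), na)
  Us <- apply(combs, 2, U_of)
  mu <- na * length(b) / 2
  mean(abs(Us - mu) >= abs(obs - mu) - 1e-12)
}

# direct-formula Pearson r and t-based p
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# independent register scorer: builds the full antiparallel alignment string
# pair-by-pair from the template, indexed from the window 3' side
oracle_register_ext <- function(window, core = "GUAGUA", e5 = "AUCAAGU",
                                e3 = "UCUGUUC", shift = 0L, bulge = NULL) {
  bonds <- c(GC = 3, CG = 3, AU = 2, UA = 2, GU = 2, UG = 2)
  bd <- function(a, b) { v <- unname(bonds[paste0(a, b)]); ifelse(is.na(v), 0, v) }
  wc <- oracle_chars(window)
  if (!is.null(bulge)) wc <- wc[-bulge]
  k <- nchar(core)
  b <- bulge
  f0 <- b - k + 1L + shift
  tmpl <- oracle_chars(paste0(e5, core, e3))
  # template position facing w' index p: guide 3' end faces window 5' end;
  # core occupies f0..f0+k-1 facing rev(core)
  core_scores <- numeric(k)
  rev_core <- rev(oracle_chars(core))
  for (i in seq_len(k)) core_scores[i] <- bd(wc[f0 + i - 1L], rev_core[i])
  ext <- 0
  e3c <- oracle_chars(e3)
  i <- 1L
  while (i <= length(e3c) && f0 - i >= 1L) {
    s <- bd(wc[f0 - i], e3c[i]); if (s == 0) break
    ext <- ext + s; i <- i + 1L
  }
  e5r <- rev(oracle_chars(e5))
  i <- 1L
  while (i <= length(e5r) && f0 + k - 1L + i <= length(wc)) {
    s <- bd(wc[f0 + k - 1L + i], e5r[i]); if (s == 0) break
    ext <- ext + s; i <- i + 1L
  }
  list(core = sum(core_scores), extended = sum(core_scores) + ext)
}

random_rna <- function(n, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}
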