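# Independent brute-force implementations used as oracles.  These are
# written from the definitions, favouring explicit loops and base
# distribution functions over the package's vectorized arithmetic.

# Conditional HWE probability of each heterozygote count, by direct
# evaluation of multinomial / hypergeometric ratios with choose().
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  n_minor <- min(nA, 2 * n - nA)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  prob <- sapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    exp(lfactorial(n) - lfactorial(hom_min) - lfactorial(h) -
          lfactorial(hom_maj) + h * log(2) +
          lfactorial(n_minor) + lfactorial(2 * n - n_minor) -
          lfactorial(2 * n))
  })
  prob <- prob / sum(prob)  # guard rounding
  sum(prob[prob <= prob[hets == n_Aa] * (1 + 1e-9)])
}

# Per-population observed/expected heterozygosity at one block, by loops.
oracle_het_block <- function(a1, a2, pops, pop) {
  rows <- which(pops == pop & !is.na(a1))
  if (length(rows) == 0) return(c(ho = NA, he = NA))
  ho <- mean(a1[rows] != a2[rows])
  alleles <- c(a1[rows], a2[rows])
  n <- length(rows)
  p <- table(alleles) / (2 * n)
  he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  c(ho = ho, he = he)
}

# Rarefaction allelic richness at one block via hypergeometric tail
# probabilities (dhyper), not lchoose arithmetic.
oracle_ar_block <- function(counts, g) {
  N <- sum(counts)
  if (N < g) return(NA)
  sum(sapply(counts[counts > 0], function(Ni)
    1 - dhyper(0, Ni, N - Ni, g)))
}

# Weir-Cockerham variance components via the ANOVA mean-square route.
oracle_wc <- function(ba, pops) {
  lev <- unique(pops)
  A <- B <- C <- 0
  for (b in seq_len(ncol(ba$A1))) {
    a1 <- ba$A1[, b]; a2 <- ba$A2[, b]
    typed <- !is.na(a1)
    ni <- sapply(lev, function(p) sum(typed & pops == p))
    use <- lev[ni >= 1]
    if (length(use) < 2) next
    ni <- ni[ni >= 1]
    ntot <- sum(ni); r <- length(use)
    nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
    for (al in unique(c(a1[typed], a2[typed]))) {
      y <- (a1 == al) + (a2 == al)          # dosage per animal
      p_i <- sapply(use, function(p) mean(y[typed & pops == p]) / 2)
      pbar <- sum(ni * p_i) / ntot
      SSG <- sum(y[typed] == 1) / 2
      SSI <- 0; SSP <- 0
      for (k in seq_along(use)) {
        yk <- y[typed & pops == use[k]]
        SSI <- SSI + 2 * sum((yk / 2 - p_i[k])^2)
        SSP <- SSP + 2 * ni[k] * (p_i[k] - pbar)^2
      }
      MSG <- SSG / ntot
      MSI <- SSI / (ntot - r)
      MSP <- SSP / (r - 1)
      A <- A + (MSP - MSI) / (2 * nc)
      B <- B + (MSI - MSG) / 2
      C <- C + MSG
    }
  }
  c(F_IS = 1 - C / (B + C), F_ST = A / (A + B + C), F_IT = 1 - C / (A + B + C))
}

# Pairwise Hs/Ht, G_ST and D_EST for two populations, plain loops.
oracle_pair_stats <- function(ba, pops, p1, p2) {
  hs <- ht <- d <- c()
  for (b in seq_len(ncol(ba$A1))) {
    a1 <- ba$A1[, b]; a2 <- ba$A2[, b]
    r1 <- which(pops == p1 & !is.na(a1))
    r2 <- which(pops == p2 & !is.na(a1))
    if (length(r1) == 0 || length(r2) == 0) next
    al <- sort(unique(c(a1[c(r1, r2)], a2[c(r1, r2)])))
    f1 <- sapply(al, function(x) sum(c(a1[r1], a2[r1]) == x)) / (2 * length(r1))
    f2 <- sapply(al, function(x) sum(c(a1[r2], a2[r2]) == x)) / (2 * length(r2))
    nh <- 2 / (1 / length(r1) + 1 / length(r2))
    hs_b <- (2 * nh / (2 * nh - 1)) * (1 - (sum(f1^2) + sum(f2^2)) / 2)
    ht_b <- 1 - sum(((f1 + f2) / 2)^2) + hs_b / (4 * nh)
    hs <- c(hs, hs_b); ht <- c(ht, ht_b)
    if (hs_b < 1) d <- c(d, 2 * (ht_b - hs_b) / (1 - hs_b))
  }
  gst <- (mean(ht) - mean(hs)) / mean(ht)
  abar <- mean(d); s2 <- var(d)
  list(gst = gst, dest = abar^3 / (abar^2 + s2))
}

# Proportion-of-shared-alleles distance by explicit multiset counting.
oracle_dps <- function(ba, i, j) {
  shared <- used <- 0
  for (b in seq_len(ncol(ba$A1))) {
    gi <- c(ba$A1[i, b], ba$A2[i, b])
    gj <- c(ba$A1[j, b], ba$A2[j, b])
    if (anyNA(gi) || anyNA(gj)) next
    used <- used + 1
    for (al in unique(c(gi, gj)))
      shared <- shared + min(sum(gi == al), sum(gj == al))
  }
  ps <- shared / (2 * used)
  if (ps > 0) -log(ps) else Inf
}
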