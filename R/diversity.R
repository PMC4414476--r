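#' Tally block-allele counts per population
#'
#' @param ba a [encode_block_alleles()] result.
#' @param populations population label per animal.
#' @return list of class `allele_counts`: `counts`, a list with one
#'   populations x alleles count matrix per block; `n_typed`, a
#'   populations x blocks matrix of genotyped diploid animals; `pops`, the
#'   population levels.
#' @export
tally_alleles <- function(ba, populations = ba$population) {
  if (any(is.na(populations))) stop("unknown population label")
  pops <- unique(populations)
  B <- ncol(ba$A1)
  counts <- vector("list", B)
  n_typed <- matrix(0L, length(pops), B, dimnames = list(pops, NULL))
  pop_f <- factor(populations, levels = pops)
  for (b in seq_len(B)) {
    K <- length(ba$codes[[b]])
    a <- c(ba$A1[, b], ba$A2[, b])
    pf <- rep(pop_f, 2)
    ok <- !is.na(a)
    tab <- table(pf[ok], factor(a[ok], levels = seq_len(K) - 1L))
    cm <- matrix(as.integer(tab), length(pops), K,
                 dimnames = list(pops, names(ba$codes[[b]])))
    counts[[b]] <- cm
    n_typed[, b] <- as.integer(table(pop_f[!is.na(ba$A1[, b])]))
  }
  structure(list(counts = counts, n_typed = n_typed, pops = pops),
            class = "allele_counts")
}

#' Classify block alleles as private, rare or common
#'
#' Each (block, allele) pair observed in the combined sample is classified
#' by the number of populations carrying it: exactly one population makes
#' it private to that population (`npA`); exactly two makes it rare,
#' credited to both carriers (`nrA`); presence in all populations makes it
#' common (`ncA`).  The per-population distinct-allele totals `nA` are
#' returned alongside.
#'
#' @param ac an [tally_alleles()] result.
#' @return list with per-population vectors `nA`, `npA`, `nrA`, and
#'   totals `ncA` (alleles observed in every population), `nA_all`
#'   (distinct alleles pooled), `nrA_distinct` (distinct rare alleles).
#' @export
partition_alleles <- function(ac) {
  pops <- ac$pops
  npop <- length(pops)
  nA <- npA <- nrA <- stats::setNames(numeric(npop), pops)
  ncA <- 0L; nA_all <- 0L; nrA_distinct <- 0L
  for (cm in ac$counts) {
    present <- cm > 0
    carriers <- colSums(present)
    observed <- carriers > 0
    nA_all <- nA_all + sum(observed)
    nA <- nA + rowSums(present)
    priv <- carriers == 1
    if (any(priv)) npA <- npA + rowSums(present[, priv, drop = FALSE])
    rare <- carriers == 2
    if (any(rare)) {
      nrA <- nrA + rowSums(present[, rare, drop = FALSE])
      nrA_distinct <- nrA_distinct + sum(rare)
    }
    ncA <- ncA + sum(carriers == npop)
  }
  list(nA = nA, npA = npA, nrA = nrA, ncA = ncA,
       nA_all = nA_all, nrA_distinct = nrA_distinct)
}

#' Observed and expected heterozygosity on block alleles
#'
#' `H_O` is the fraction of genotyped animals whose two block alleles
#' differ, averaged over blocks.  `H_E` is Nei's unbiased expected
#' heterozygosity, `(2n/(2n-1)) * (1 - sum p^2)` with `n` genotyped diploid
#' animals per (block, population), averaged over blocks.
#'
#' @param ba a [encode_block_alleles()] result.
#' @param populations population label per animal.
#' @return data.frame with one row per population: `H_O`, `H_E`.
#' @export
heterozygosity <- function(ba, populations = ba$population) {
  ac <- tally_alleles(ba, populations)
  pops <- ac$pops
  B <- length(ac$counts)
  ho <- he <- matrix(NA_real_, length(pops), B)
  pop_f <- factor(populations, levels = pops)
  for (b in seq_len(B)) {
    het <- ba$A1[, b] != ba$A2[, b]
    ho[, b] <- tapply(het, pop_f, mean, na.rm = TRUE)
    n <- ac$n_typed[, b]
    cm <- ac$counts[[b]]
    p2 <- rowSums((cm / pmax(2 * n, 1))^2)
    he[, b] <- ifelse(n >= 1, (2 * n / pmax(2 * n - 1, 1)) * (1 - p2), NA)
  }
  data.frame(population = pops,
             H_O = rowMeans(ho, na.rm = TRUE),
             H_E = rowMeans(he, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

#' Observed heterozygosity from single-SNP genotypes
#'
#' Fraction of heterozygous SNP genotypes per animal (over its genotyped
#' SNPs), averaged within population.
#'
#' @param haps phased haplotype object.
#' @param populations population label per animal.
#' @return named numeric vector per population.
#' @export
snp_observed_heterozygosity <- function(haps, populations = haps$population) {
  het <- haps$H1 != haps$H2
  per_animal <- rowMeans(het, na.rm = TRUE)
  per_animal[is.nan(per_animal)] <- 0
  tapply(per_animal, factor(populations, levels = unique(populations)), mean)
}

#' Rarefaction allelic richness
#'
#' Expected number of distinct alleles in a standardized subsample of `g`
#' gene copies, by hypergeometric rarefaction:
#' `AR(block, pop) = sum_i [1 - C(N - N_i, g) / C(N, g)]` with `N` gene
#' copies of which `N_i` carry allele `i`; averaged over blocks.  Blocks
#' where a population has fewer than `g` copies are excluded from that
#' population's mean.
#'
#' @param ac an [tally_alleles()] result.
#' @param g standardized gene-copy count; defaults to the smallest
#'   positive (block, population) gene-copy total.
#' @return named numeric vector per population, with attribute `g`.
#' @export
allelic_richness <- function(ac, g = NULL) {
  copies <- 2 * ac$n_typed
  if (is.null(g)) g <- min(copies[copies > 0])
  if (g < 2) stop("g must be at least 2")
  pops <- ac$pops
  B <- length(ac$counts)
  ar <- matrix(NA_real_, length(pops), B)
  for (b in seq_len(B)) {
    cm <- ac$counts[[b]]
    N <- rowSums(cm)
    for (k in seq_along(pops)) {
      if (N[k] < g) next
      Ni <- cm[k, ]
      Ni <- Ni[Ni > 0]
      ar[k, b] <- sum(1 - exp(lchoose(N[k] - Ni, g) - lchoose(N[k], g)))
    }
  }
  out <- rowMeans(ar, na.rm = TRUE)
  names(out) <- pops
  attr(out, "g") <- g
  out
}

#' Multilocus Weir-Cockerham F-statistics on block alleles
#'
#' Variance components (a, b, c) are computed per allele per block from
#' the within-population allele frequencies and observed heterozygote
#' proportions, summed over alleles and blocks:
#' `F_ST = sum(a) / sum(a+b+c)`, `F_IS = 1 - sum(c)/sum(b+c)`,
#' `F_IT = 1 - sum(c)/sum(a+b+c)`.
#'
#' @param ba a [encode_block_alleles()] result.
#' @param populations population label per animal.
#' @param pairs optional character vector restricting to a subset of
#'   populations.
#' @return named numeric vector `c(F_IS, F_ST, F_IT)` with attribute
#'   `components` (summed a, b, c).
#' @export
wc_fstats <- function(ba, populations = ba$population, pairs = NULL) {
  if (!is.null(pairs)) {
    keep <- populations %in% pairs
    ba <- subset_animals(ba, keep)
    populations <- populations[keep]
  }
  pops <- unique(populations)
  if (length(pops) < 2) stop("at least two populations required")
  if (any(table(populations) < 2)) stop("each population needs >= 2 animals")
  pop_f <- factor(populations, levels = pops)
  A <- 0; Bv <- 0; Cv <- 0
  for (b in seq_len(ncol(ba$A1))) {
    a1 <- ba$A1[, b]; a2 <- ba$A2[, b]
    typed <- !is.na(a1)
    if (!any(typed)) next
    ni <- tapply(typed, pop_f, sum)
    use <- which(ni >= 1)
    if (length(use) < 2) next
    r <- length(use)
    ni <- as.numeric(ni[use])
    nbar <- mean(ni)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    alleles <- sort(unique(c(a1[typed], a2[typed])))
    for (al in alleles) {
      cnt <- tapply((a1 == al) + (a2 == al), pop_f, sum, na.rm = TRUE)[use]
      p_i <- as.numeric(cnt) / (2 * ni)
      hobs <- tapply(((a1 == al) + (a2 == al)) == 1, pop_f,
                     sum, na.rm = TRUE)[use]
      h_i <- as.numeric(hobs) / ni
      pbar <- sum(ni * p_i) / (r * nbar)
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h_i) / (r * nbar)
      a_c <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b_c <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      c_c <- hbar / 2
      A <- A + a_c; Bv <- Bv + b_c; Cv <- Cv + c_c
    }
  }
  tot <- A + Bv + Cv
  out <- c(F_IS = 1 - Cv / (Bv + Cv), F_ST = A / tot, F_IT = 1 - Cv / tot)
  attr(out, "components") <- c(a = A, b = Bv, c = Cv)
  out
}

# internal: subset a block_alleles object by animal
subset_animals <- function(ba, keep) {
  out <- ba
  out$animal_id <- ba$animal_id[keep]
  out$population <- ba$population[keep]
  out$A1 <- ba$A1[keep, , drop = FALSE]
  out$A2 <- ba$A2[keep, , drop = FALSE]
  out
}

# internal: per-block unbiased Hs/Ht estimates for one population pair,
# following the small-sample corrections used for diploid data:
#   Hs_est = (2*Nh / (2*Nh - 1)) * (1 - mean_k sum_i p_ki^2)
#   Ht_est = 1 - sum_i pbar_i^2 + Hs_est / (4 * Nh)
# with Nh the harmonic mean of the two sample sizes.
.pair_hs_ht <- function(ac, i, j) {
  B <- length(ac$counts)
  hs <- ht <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    n1 <- ac$n_typed[i, b]; n2 <- ac$n_typed[j, b]
    if (n1 < 1 || n2 < 1) next
    cm <- ac$counts[[b]]
    p1 <- cm[i, ] / (2 * n1); p2 <- cm[j, ] / (2 * n2)
    nh <- 2 / (1 / n1 + 1 / n2)
    hs_raw <- 1 - (sum(p1^2) + sum(p2^2)) / 2
    pbar <- (p1 + p2) / 2
    hs[b] <- (2 * nh / (2 * nh - 1)) * hs_raw
    ht[b] <- 1 - sum(pbar^2) + hs[b] / (4 * nh)
  }
  list(hs = hs, ht = ht)
}

#' Pairwise multilocus G_ST between populations
#'
#' Per block and pair, the within-pair gene diversity `H_S` is the
#' unweighted mean of the two populations' unbiased gene diversities and
#' `H_T` the unbiased gene diversity of the unweighted mean allele
#' frequencies (Nei-Chesser small-sample corrections).  The multilocus
#' value is `(mean(H_T) - mean(H_S)) / mean(H_T)` over blocks.
#'
#' @param ac an [tally_alleles()] result.
#' @return symmetric matrix with attribute `kind = "GST"`, zero diagonal.
#' @export
gst_pairwise <- function(ac) {
  pops <- ac$pops
  if (length(pops) < 2) stop("at least two populations required")
  M <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1)) {
    hh <- .pair_hs_ht(ac, i, j)
    hs_bar <- mean(hh$hs, na.rm = TRUE)
    ht_bar <- mean(hh$ht, na.rm = TRUE)
    M[i, j] <- M[j, i] <- (ht_bar - hs_bar) / ht_bar
  }
  attr(M, "kind") <- "GST"
  M
}

#' Pairwise multilocus Jost's D_EST between populations
#'
#' Per block, `D = (H_T - H_S) / (1 - H_S) * n/(n-1)` with `n = 2`
#' populations and the same unbiased `H_S`, `H_T` as [gst_pairwise()].
#' Blocks with `H_S = 1` (undefined D) are excluded.  Across blocks the
#' values are combined by the variance-corrected harmonic mean
#' `1 / (1/A + s^2 / A^3) = A^3 / (A^2 + s^2)` where `A` and `s^2` are the
#' arithmetic mean and variance of the per-block values; negative
#' per-block values are retained.
#'
#' @param ac an [tally_alleles()] result.
#' @return symmetric matrix with attribute `kind = "DEST"`, zero diagonal.
#' @export
dest_pairwise <- function(ac) {
  pops <- ac$pops
  if (length(pops) < 2) stop("at least two populations required")
  M <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1)) {
    hh <- .pair_hs_ht(ac, i, j)
    d <- 2 * (hh$ht - hh$hs) / (1 - hh$hs)
    d <- d[is.finite(d)]
    abar <- mean(d)
    s2 <- stats::var(d)
    M[i, j] <- M[j, i] <- abar^3 / (abar^2 + s2)
  }
  attr(M, "kind") <- "DEST"
  M
}

#' Per-population block allele frequencies
#'
#' @param ac an [tally_alleles()] result.
#' @return list with one populations x alleles frequency matrix per block
#'   (rows with zero gene copies are `NA`).
#' @export
block_frequencies <- function(ac) {
  lapply(seq_along(ac$counts), function(b) {
    cm <- ac$counts[[b]]
    copies <- 2 * ac$n_typed[, b]
    f <- cm / copies
    f[copies == 0, ] <- NA
    f
  })
}

#' Assemble the per-breed diversity summary table
#'
#' One row per population plus a pooled `All` row.  `mA = nA / B` with `B`
#' the realized block count (monomorphic blocks retained in the
#' denominator).  In the `All` row, `nA` and `mA` are pooled over
#' populations, `npA` is the sum of per-population private alleles, `nrA`
#' the number of distinct rare alleles, and the heterozygosities and
#' allelic richness are unweighted means over populations.
#'
#' @param ba a [encode_block_alleles()] result.
#' @param haps phased haplotype object on the same panel (for the
#'   single-SNP observed heterozygosity column); may be `NULL`.
#' @param populations population label per animal.
#' @param g rarefaction depth passed to [allelic_richness()].
#' @return data.frame of class `diversity_table`.
#' @export
summarize_diversity <- function(ba, haps = NULL,
                                populations = ba$population, g = NULL) {
  ac <- tally_alleles(ba, populations)
  B <- length(ac$counts)
  part <- partition_alleles(ac)
  het <- heterozygosity(ba, populations)
  ar <- allelic_richness(ac, g)
  ho_snp <- if (is.null(haps)) rep(NA_real_, length(ac$pops))
            else as.numeric(snp_observed_heterozygosity(haps, populations))
  N <- as.integer(table(factor(populations, levels = ac$pops)))
  tab <- data.frame(population = ac$pops, N = N,
                    nA = as.integer(part$nA),
                    mA = part$nA / B,
                    npA = as.integer(part$npA),
                    nrA = as.integer(part$nrA),
                    H_O = het$H_O, H_O_snp = ho_snp, H_E = het$H_E,
                    AR = as.numeric(ar), stringsAsFactors = FALSE)
  all_row <- data.frame(population = "All", N = sum(N),
                        nA = as.integer(part$nA_all),
                        mA = part$nA_all / B,
                        npA = as.integer(sum(part$npA)),
                        nrA = as.integer(part$nrA_distinct),
                        H_O = mean(tab$H_O), H_O_snp = mean(ho_snp),
                        H_E = mean(tab$H_E), AR = mean(tab$AR),
                        stringsAsFactors = FALSE)
  out <- rbind(tab, all_row)
  attr(out, "n_blocks") <- B
  attr(out, "ncA") <- part$ncA
  attr(out, "g") <- attr(ar, "g")
  class(out) <- c("diversity_table", "data.frame")
  out
}
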