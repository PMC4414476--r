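#' QC thresholds for SNP filtering
#'
#' @param min_call_rate minimum proportion of genotyped animals per SNP.
#' @param min_maf minimum pooled minor-allele frequency.
#' @param hwe_alpha within-breed Hardy-Weinberg exact-test significance
#'   level below which a SNP is removed.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.025,
                          hwe_alpha = 0.01) {
  stopifnot(min_call_rate > 0, min_call_rate < 1,
            min_maf > 0, min_maf < 1, hwe_alpha > 0, hwe_alpha < 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha), class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium for a biallelic SNP
#'
#' Two-sided conditional exact test: given the sample size and the minor
#' allele count, the probability of each possible heterozygote count (same
#' parity as the observed one) is computed, and the p-value is the sum of
#' probabilities of all configurations no more probable than the observed
#' one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all-zero genotype counts")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  n_minor <- min(nA, na)
  if (n_minor == 0) return(1)                  # monomorphic: one configuration
  hets <- seq(n_minor %% 2, n_minor, by = 2)   # feasible het counts, same parity
  # log P(het = h | n, nA) up to a constant: multinomial x 2^h
  lp <- vapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    lgamma(n + 1) - lgamma(hom_minor + 1) - lgamma(h + 1) -
      lgamma(hom_major + 1) + h * log(2)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

#' Filter SNPs by call rate, pooled MAF and within-breed HWE
#'
#' A SNP is retained when its call rate over the combined sample is at
#' least `min_call_rate`, its pooled minor allele frequency is at least
#' `min_maf`, and its within-breed Hardy-Weinberg exact p-value is at least
#' `hwe_alpha` in every breed with at least 10 genotyped animals at that
#' SNP.  The returned panel keeps the input order; its `"index"` attribute
#' holds the original column indices and its `"qc_log"` attribute a
#' per-SNP data.frame of reason codes.
#'
#' @param panel SNP map data.frame.
#' @param haps phased haplotype object aligned to `panel`.
#' @param populations population label per animal (defaults to
#'   `haps$population`).
#' @param thresholds a [qc_thresholds()] object.
#' @param min_hwe_n smallest within-breed genotyped sample for which the
#'   HWE test is applied.
#' @return filtered panel (same columns, attributes `index` and `qc_log`).
#' @export
filter_snps <- function(panel, haps, populations = haps$population,
                        thresholds = qc_thresholds(), min_hwe_n = 10) {
  m <- nrow(panel)
  stopifnot(ncol(haps$H1) == m)
  n <- nrow(haps$H1)
  typed <- !is.na(haps$H1)
  call_rate <- colSums(typed) / n
  alt_count <- colSums(haps$H1, na.rm = TRUE) + colSums(haps$H2, na.rm = TRUE)
  copies <- 2 * colSums(typed)
  af <- ifelse(copies > 0, alt_count / copies, NA)
  maf <- pmin(af, 1 - af)

  hwe_fail <- rep(FALSE, m)
  for (pop in unique(populations)) {
    rows <- which(populations == pop)
    if (length(rows) < min_hwe_n) next
    g <- haps$H1[rows, , drop = FALSE] + haps$H2[rows, , drop = FALSE]
    n_typed <- colSums(!is.na(g))
    test_cols <- which(n_typed >= min_hwe_n)
    for (j in test_cols) {
      gj <- g[, j]
      n_aa <- sum(gj == 0, na.rm = TRUE)
      n_het <- sum(gj == 1, na.rm = TRUE)
      n_AA <- sum(gj == 2, na.rm = TRUE)
      if (hwe_exact_test(n_AA, n_het, n_aa) < thresholds$hwe_alpha)
        hwe_fail[j] <- TRUE
    }
  }

  low_call <- call_rate < thresholds$min_call_rate
  low_maf <- is.na(maf) | maf < thresholds$min_maf
  keep <- !(low_call | low_maf | hwe_fail)
  if (!any(keep)) stop("empty panel after filtering")
  reason <- rep("pass", m)
  reason[hwe_fail] <- "hwe"
  reason[low_maf] <- "maf"
  reason[low_call] <- "call_rate"
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "index") <- which(keep)
  attr(out, "qc_log") <- data.frame(snp_id = panel$snp_id,
                                    call_rate = call_rate, maf = maf,
                                    hwe_fail = hwe_fail, reason = reason,
                                    kept = keep, stringsAsFactors = FALSE)
  out
}
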