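#' Genome-wide relationship matrix from SNP genotypes
#'
#' Allele-frequency-standardized relationships reconciling identity by
#' state with identity by descent.  With genotype dosage `x` in `{0,1,2}`
#' and pooled-sample allele frequency `p` per SNP:
#' off-diagonal `g_ij = mean_snps (x_i - 2p)(x_j - 2p) / (2p(1-p))`,
#' diagonal `g_ii = 1 + mean_snps (x_i^2 - (1+2p)x_i + 2p^2) / (2p(1-p))`
#' (approximately one plus the inbreeding coefficient).  SNPs monomorphic
#' in the sample are excluded; per pair, only SNPs genotyped in both
#' animals contribute.
#'
#' @param haps phased haplotype object.
#' @return symmetric matrix with animal-id dimnames, attribute
#'   `kind = "REL"`.
#' @export
genomic_relationship <- function(haps) {
  X <- haps$H1 + haps$H2
  n <- nrow(X)
  if (n < 2) stop("at least two animals required")
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- which(p > 0 & p < 1 & !is.na(p))
  if (length(poly) == 0) stop("monomorphic panel")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  denom <- 2 * p * (1 - p)
  Z <- sweep(X, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(denom), "/")
  obs <- !is.na(Z)
  Z0 <- Z; Z0[!obs] <- 0
  pairs_n <- tcrossprod(obs * 1)
  G <- tcrossprod(Z0) / pairs_n
  # diagonal: one plus estimated inbreeding
  Dterm <- X^2 - sweep(X, 2, 1 + 2 * p, "*") +
    matrix(2 * p^2, n, length(p), byrow = TRUE)
  Dterm <- sweep(Dterm, 2, denom, "/")
  diag(G) <- 1 + rowMeans(Dterm, na.rm = TRUE)
  dimnames(G) <- list(haps$animal_id, haps$animal_id)
  attr(G, "kind") <- "REL"
  G
}

#' Mean genomic relationship of one animal to a population
#'
#' Arithmetic mean of the off-diagonal relationship entries between
#' `animal` and the members of `population`, excluding the animal itself.
#'
#' @param G relationship matrix with animal-id dimnames.
#' @param animal animal id.
#' @param members ids of the population's animals.
#' @return scalar mean relationship.
#' @export
mean_relationship_to_population <- function(G, animal, members) {
  members <- setdiff(members, animal)
  if (length(members) == 0) stop("empty population")
  mean(G[animal, members])
}
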