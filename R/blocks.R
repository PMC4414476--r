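#' Partition a SNP panel into non-overlapping 4-SNP haplotype blocks
#'
#' Greedy left-to-right scan within each chromosome: a run of consecutive
#' SNPs is extended while the gap to the next SNP is below `max_gap`; every
#' time the run reaches `block_size` SNPs a block is emitted and the run
#' restarts; a gap of `max_gap` or more resets the run; leftover runs
#' shorter than `block_size` are discarded.  With the 50 kb default each
#' block spans less than 150 kb.
#'
#' @param panel SNP map data.frame, sorted by chromosome and position.
#' @param max_gap largest allowed adjacent inter-marker distance in bp.
#' @param block_size SNPs per block.
#' @return data.frame of class `block_set` with columns `chrom`, `start`,
#'   `end` (bp of first and last member SNP) and an `idx` matrix column of
#'   panel row indices.
#' @export
build_blocks <- function(panel, max_gap = 50000, block_size = 4) {
  if (nrow(panel) == 0) stop("empty panel")
  o <- order(panel$chrom, panel$pos)
  if (any(o != seq_len(nrow(panel)))) stop("panel must be sorted")
  blocks <- list()
  for (ch in unique(panel$chrom)) {
    rows <- which(panel$chrom == ch)
    run <- integer(0)
    for (i in rows) {
      if (length(run) > 0 &&
          panel$pos[i] - panel$pos[run[length(run)]] >= max_gap)
        run <- integer(0)
      run <- c(run, i)
      if (length(run) == block_size) {
        blocks[[length(blocks) + 1]] <- run
        run <- integer(0)
      }
    }
  }
  idx <- do.call(rbind, blocks)
  if (is.null(idx)) idx <- matrix(integer(0), 0, block_size)
  out <- data.frame(chrom = panel$chrom[idx[, 1]],
                    start = panel$pos[idx[, 1]],
                    end = panel$pos[idx[, ncol(idx)]],
                    stringsAsFactors = FALSE)
  stopifnot(all(out$end - out$start < (block_size - 1) * max_gap))
  out$idx <- idx
  class(out) <- c("block_set", "data.frame")
  out
}

#' Encode each animal's two block haplotypes as multi-allelic alleles
#'
#' Within each block, the 4-symbol haplotype strings observed across the
#' combined sample are mapped to dense integer codes in order of first
#' appearance (animal order, first then second haplotype).  An animal with
#' a missing allele at any member SNP has that block genotype flagged
#' absent (`NA` on both codes).
#'
#' @param haps phased haplotype object aligned to the panel used for
#'   `blocks`.
#' @param blocks a [build_blocks()] result.
#' @return list of class `block_alleles` with `animal_id`, `population`,
#'   integer matrices `A1`, `A2` (animals x blocks) and `codes`, a list of
#'   named code vectors per block.
#' @export
encode_block_alleles <- function(haps, blocks) {
  n <- nrow(haps$H1)
  B <- nrow(blocks)
  A1 <- matrix(NA_integer_, n, B)
  A2 <- matrix(NA_integer_, n, B)
  codes <- vector("list", B)
  for (b in seq_len(B)) {
    snps <- blocks$idx[b, ]
    s1 <- apply(haps$H1[, snps, drop = FALSE], 1, paste, collapse = "")
    s2 <- apply(haps$H2[, snps, drop = FALSE], 1, paste, collapse = "")
    miss <- grepl("NA", s1, fixed = TRUE) | grepl("NA", s2, fixed = TRUE)
    s1[miss] <- NA; s2[miss] <- NA
    # first-appearance order over the interleaved sequence h1_1, h2_1, h1_2, ...
    inter <- as.vector(rbind(s1, s2))
    lev <- unique(inter[!is.na(inter)])
    A1[, b] <- match(s1, lev) - 1L
    A2[, b] <- match(s2, lev) - 1L
    codes[[b]] <- stats::setNames(seq_along(lev) - 1L, lev)
  }
  out <- list(animal_id = haps$animal_id, population = haps$population,
              A1 = A1, A2 = A2, codes = codes, blocks = blocks)
  class(out) <- "block_alleles"
  out
}
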