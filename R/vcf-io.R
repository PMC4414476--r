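#' Write phased haplotypes to a minimal VCF
#'
#' Emits a VCFv4.2 file with GT-only FORMAT and `|`-separated phased
#' genotypes.  Missing genotypes are written as `.|.`.
#'
#' @param panel SNP map data.frame with columns `chrom`, `pos`, `snp_id`,
#'   `ref`, `alt`.
#' @param haps phased haplotype object (`animal_id`, `population`, `H1`, `H2`).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_phased_vcf <- function(panel, haps, path) {
  n <- length(haps$animal_id)
  m <- nrow(panel)
  stopifnot(ncol(haps$H1) == m, ncol(haps$H2) == m)
  gt <- matrix(paste0(haps$H1, "|", haps$H2), n, m)
  gt[is.na(haps$H1) | is.na(haps$H2)] <- ".|."
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste0("##source=hapdiv ", as.character(utils::packageVersion("hapdiv"))),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", haps$animal_id), collapse = "\t"))
  body <- paste(panel$chrom, panel$pos, panel$snp_id, panel$ref, panel$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF into a SNP panel and haplotype matrices
#'
#' Requires every genotype to be phased diploid (`a|b` or `.|.`).  An
#' unphased (`/`-separated) or non-diploid record is an error, as is a
#' duplicated position within a chromosome.  Population labels are taken
#' from `populations` (named by sample) when given, otherwise set to `"NA"`.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param populations optional named character vector mapping sample id to
#'   population label.
#' @return list with `panel` and `haplotypes` as produced by
#'   [simulate_panel()].
#' @export
read_phased_vcf <- function(path, populations = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record file
  panel <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      snp_id = fix[, "ID"],
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  if (anyDuplicated(panel[, c("chrom", "pos")]))
    stop("duplicated position in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")        # SNPs x samples
  gt[is.na(gt)] <- ".|."                           # vcfR masks missing GT
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotype in VCF (found '/' separator)")
  ok <- grepl("^(\\.\\|\\.|[0-9]+\\|[0-9]+)$", gt)
  if (!all(ok)) stop("non-diploid or malformed genotype: ",
                     gt[which(!ok)[1]])
  samples <- colnames(gt)
  a1 <- sub("\\|.*", "", gt); a2 <- sub(".*\\|", "", gt)
  a1[a1 == "."] <- NA; a2[a2 == "."] <- NA
  H1 <- t(matrix(as.integer(a1), nrow(gt), ncol(gt)))
  H2 <- t(matrix(as.integer(a2), nrow(gt), ncol(gt)))
  miss <- is.na(H1) | is.na(H2)
  H1[miss] <- NA_integer_; H2[miss] <- NA_integer_
  pops <- if (is.null(populations)) rep(NA_character_, length(samples))
          else unname(populations[samples])
  ord <- order(panel$chrom, panel$pos)
  panel <- panel[ord, , drop = FALSE]
  rownames(panel) <- NULL
  haps <- list(animal_id = samples, population = pops,
               H1 = H1[, ord, drop = FALSE], H2 = H2[, ord, drop = FALSE])
  class(haps) <- "phased_haps"
  list(panel = panel, haplotypes = haps)
}

#' Subset phased haplotypes to the SNPs of a (filtered) panel
#'
#' @param haps phased haplotype object.
#' @param keep integer vector of panel column indices to retain (for a
#'   filtered panel, its `"index"` attribute).
#' @return the subset haplotype object.
#' @export
subset_haplotypes <- function(haps, keep) {
  if (!is.null(attr(keep, "index"))) keep <- attr(keep, "index")
  out <- haps
  out$H1 <- haps$H1[, keep, drop = FALSE]
  out$H2 <- haps$H2[, keep, drop = FALSE]
  out
}
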