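#' Bundled reference tables from a 15-breed cattle SNP-array survey
#'
#' The package ships two published summary tables from a medium-density
#' SNP-array survey of 15 European and African taurine cattle breeds, the
#' study design the synthetic generator's defaults emulate:
#' `cattle_diversity_15breeds.csv` (per-breed N, nA, mA, npA, nrA, H_O,
#' H_O from SNPs, H_E, AR, plus a pooled `All` row) and
#' `cattle_differentiation_15breeds.csv` (pairwise D_EST above the
#' diagonal, G_ST below, with row-average D_EST and column-average G_ST
#' margins).  They serve as worked-example inputs for the table arithmetic
#' the statistics reproduce (mA ratios, allele-class bookkeeping, row
#' averages, the D_EST-G_ST concordance).
#'
#' @return list with `diversity` (data.frame), `dest` and `gst` (symmetric
#'   15 x 15 matrices), `dbar_est` (named row-average D_EST), `gbar_st`
#'   (named average G_ST).
#' @export
load_reference_tables <- function() {
  div <- utils::read.csv(system.file("extdata",
                                     "cattle_diversity_15breeds.csv",
                                     package = "hapdiv"),
                         stringsAsFactors = FALSE)
  raw <- utils::read.csv(system.file("extdata",
                                     "cattle_differentiation_15breeds.csv",
                                     package = "hapdiv"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  breeds <- raw$breed[raw$breed != "Gbar_ST"]
  body <- as.matrix(raw[raw$breed != "Gbar_ST", breeds])
  rownames(body) <- breeds
  dest <- gst <- matrix(NA_real_, length(breeds), length(breeds),
                        dimnames = list(breeds, breeds))
  ut <- upper.tri(dest)
  dest[ut] <- body[ut]; dest <- pmax(dest, t(dest), na.rm = TRUE)
  lt <- lower.tri(gst)
  gst[lt] <- body[lt]; gst <- pmax(gst, t(gst), na.rm = TRUE)
  diag(dest) <- diag(gst) <- 0
  dbar <- stats::setNames(raw$Dbar_EST[raw$breed != "Gbar_ST"], breeds)
  gbar <- stats::setNames(as.numeric(raw[raw$breed == "Gbar_ST", breeds]),
                          breeds)
  list(diversity = div, dest = dest, gst = gst,
       dbar_est = dbar, gbar_st = gbar)
}
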