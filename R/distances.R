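#' Nei's D_A distance between populations
#'
#' `D_A(x, y) = 1 - (1/L) * sum_blocks sum_alleles sqrt(x_i * y_i)`.
#' Blocks where either population has no gene copies are excluded from `L`
#' for that pair.
#'
#' @param freqs a [block_frequencies()] result.
#' @return symmetric matrix with zero diagonal, attribute `kind = "DA"`.
#' @export
nei_da <- function(freqs) {
  pops <- rownames(freqs[[1]])
  if (length(pops) < 2) stop("at least two populations required")
  M <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1)) {
    aff <- vapply(freqs, function(f) {
      x <- f[i, ]; y <- f[j, ]
      if (anyNA(x) || anyNA(y)) return(NA_real_)
      sum(sqrt(x * y))
    }, numeric(1))
    M[i, j] <- M[j, i] <- 1 - mean(aff, na.rm = TRUE)
  }
  attr(M, "kind") <- "DA"
  M
}

#' Proportion-of-shared-alleles distance between individuals
#'
#' `PS(i, j)` is the mean over blocks of `s/2`, where `s` in `{0, 1, 2}`
#' counts alleles shared with multiplicity between the two animals' block
#' genotypes (multiset intersection: A/A vs A/B share 1, A/A vs A/A share
#' 2).  Blocks absent in either animal are excluded for that pair.  The
#' distance is `-ln(PS)`; pairs with `PS = 0` get `+Inf`.
#'
#' @param ba a [encode_block_alleles()] result.
#' @return symmetric matrix with zero diagonal, attribute `kind = "DPS"`,
#'   dimnames from animal ids.
#' @export
dps_individuals <- function(ba) {
  n <- nrow(ba$A1)
  if (n < 2) stop("at least two animals required")
  if (any(rowSums(!is.na(ba$A1)) == 0))
    stop("animal with all block genotypes absent")
  ids <- ba$animal_id
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  A1 <- ba$A1; A2 <- ba$A2
  for (i in seq_len(n)) {
    x1 <- A1[i, ]; x2 <- A2[i, ]
    for (j in seq_len(i - 1)) {
      y1 <- A1[j, ]; y2 <- A2[j, ]
      ok <- !is.na(x1) & !is.na(y1)
      m1 <- (x1 == y1) + (x2 == y2)
      m2 <- (x1 == y2) + (x2 == y1)
      s <- pmax(m1, m2)[ok]
      ps <- mean(s) / 2
      M[i, j] <- M[j, i] <- if (ps > 0) -log(ps) else Inf
    }
  }
  attr(M, "kind") <- "DPS"
  M
}

#' Export a distance matrix in PHYLIP or NEXUS format
#'
#' Writes a square PHYLIP distance matrix (dimension header line, then one
#' row per taxon) or a NEXUS `DISTANCES` block, both parseable by standard
#' phylogenetics software.  Infinite entries are replaced by 1.1 times the
#' largest finite entry, with a message.
#'
#' @param m symmetric distance matrix with dimnames.
#' @param path output file.
#' @param format `"phylip"` or `"nexus"`.
#' @return invisibly, `path`.
#' @export
export_distance <- function(m, path, format = c("phylip", "nexus")) {
  format <- match.arg(format)
  if (nrow(m) == 0) stop("empty matrix")
  if (any(!is.finite(m))) {
    cap <- max(m[is.finite(m)]) * 1.1
    message("replacing ", sum(!is.finite(m)), " infinite entries by ", cap)
    m[!is.finite(m)] <- cap
  }
  labels <- gsub("[[:space:]]", "_", rownames(m))
  if (format == "phylip") {
    lines <- c(sprintf("%5d", nrow(m)),
               vapply(seq_len(nrow(m)), function(i)
                 paste(formatC(labels[i], width = -10),
                       paste(sprintf("%.6f", m[i, ]), collapse = "  ")),
                 character(1)))
  } else {
    lines <- c("#NEXUS", "",
               "BEGIN TAXA;",
               sprintf("  DIMENSIONS NTAX=%d;", nrow(m)),
               paste0("  TAXLABELS ", paste(labels, collapse = " "), ";"),
               "END;", "",
               "BEGIN DISTANCES;",
               "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;",
               "  MATRIX",
               vapply(seq_len(nrow(m)), function(i)
                 paste0("    ", formatC(labels[i], width = -10), " ",
                        paste(sprintf("%.6f", m[i, ]), collapse = " ")),
                 character(1)),
               "  ;", "END;")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' Companion reader to [export_distance()] for round-trip checks.
#'
#' @param path PHYLIP distance file.
#' @return symmetric matrix with dimnames.
#' @export
read_phylip_distance <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[2:(n + 1)]), "[[:space:]]+")
  labels <- vapply(parts, `[`, character(1), 1)
  M <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
  dimnames(M) <- list(labels, labels)
  M
}
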