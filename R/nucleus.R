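#' Breed composition from pedigree records
#'
#' Founders (both parents unknown, breed label recorded) contribute 100%
#' of their labelled breed; every other animal is the average of its
#' parents' compositions.  An unknown parent is treated as a purebred
#' founder of the focal breed and the animal is flagged
#' `pedigree_incomplete`, mirroring the herd-book convention of recording
#' animals without pedigree as purebred.
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam`, `breed`
#'   (founder breed label, `NA` for non-founders).
#' @param focal focal breed label used for unknown parents.
#' @return list: `fractions`, an animals x breeds matrix of breed
#'   fractions; `incomplete`, a named logical vector.
#' @export
pedigree_breed_composition <- function(pedigree, focal) {
  ped <- pedigree
  ped[ped == ""] <- NA
  breeds <- sort(unique(c(focal, stats::na.omit(ped$breed))))
  n <- nrow(ped)
  frac <- matrix(0, n, length(breeds), dimnames = list(ped$id, breeds))
  incomplete <- stats::setNames(rep(FALSE, n), ped$id)
  done <- stats::setNames(rep(FALSE, n), ped$id)
  focal_vec <- stats::setNames(as.numeric(breeds == focal), breeds)

  resolve <- function(id, chain = character(0)) {
    if (id %in% chain) stop("cycle detected in pedigree at ", id)
    if (done[id]) return(frac[id, ])
    row <- which(ped$id == id)[1]
    s <- ped$sire[row]; d <- ped$dam[row]
    if (is.na(s) && is.na(d) && !is.na(ped$breed[row])) {
      f <- stats::setNames(as.numeric(breeds == ped$breed[row]), breeds)
    } else {
      getp <- function(p) {
        if (is.na(p) || !p %in% ped$id) {
          incomplete[id] <<- TRUE
          focal_vec
        } else {
          if (!done[p]) {
            val <- resolve(p, c(chain, id))
            incomplete[id] <<- incomplete[id] || incomplete[p]
            val
          } else {
            incomplete[id] <<- incomplete[id] || incomplete[p]
            frac[p, ]
          }
        }
      }
      f <- (getp(s) + getp(d)) / 2
    }
    frac[id, ] <<- f
    done[id] <<- TRUE
    f
  }
  for (id in ped$id) resolve(id)
  list(fractions = frac, incomplete = incomplete)
}

#' Supervised admixture-fraction estimation by EM
#'
#' Reference allele frequencies are estimated per reference population
#' from its genotyped animals and clamped into `freq_bound`.  For each
#' focal animal the log-likelihood
#' `sum_snps [x log(sum_k q_k f_k) + (2-x) log(sum_k q_k (1-f_k))]`
#' is maximized over the ancestry simplex by EM from a uniform start;
#' convergence when `max |dq| < tol`.  If the reference populations are
#' (near) indistinguishable at every SNP the likelihood is flat; the
#' estimate is then unidentifiable and a `degenerate` flag is set.
#'
#' @param haps phased haplotype object (reference and focal animals).
#' @param reference_populations labels of the reference populations.
#' @param focal_animals ids of the animals whose ancestry is estimated.
#' @param tol convergence tolerance on the ancestry update.
#' @param max_iter EM iteration cap; non-convergence is reported via the
#'   `converged` attribute and the last iterate returned.
#' @param freq_bound reference-frequency clamp.
#' @return matrix (focal animals x reference populations) of ancestry
#'   fractions summing to one per row; attributes `converged`,
#'   `iterations`, `degenerate`.
#' @export
supervised_admixture <- function(haps, reference_populations, focal_animals,
                                 tol = 1e-6, max_iter = 1000,
                                 freq_bound = c(0.001, 0.999)) {
  K <- length(reference_populations)
  if (K < 2) stop("at least two reference populations required")
  X <- haps$H1 + haps$H2
  m <- ncol(X)
  Fm <- matrix(NA_real_, m, K, dimnames = list(NULL, reference_populations))
  for (k in seq_len(K)) {
    rows <- which(haps$population == reference_populations[k])
    if (length(rows) == 0) stop("no animals in reference population ",
                                reference_populations[k])
    Fm[, k] <- colMeans(X[rows, , drop = FALSE], na.rm = TRUE) / 2
  }
  Fm[is.na(Fm)] <- 0.5
  Fm <- pmin(pmax(Fm, freq_bound[1]), freq_bound[2])
  degenerate <- max(apply(Fm, 1, function(r) diff(range(r)))) < 1e-8
  if (degenerate)
    warning("reference populations are indistinguishable; ",
            "ancestry fractions are unidentifiable")

  rows <- match(focal_animals, haps$animal_id)
  if (anyNA(rows)) stop("unknown focal animal id")
  Q <- matrix(NA_real_, length(rows), K,
              dimnames = list(focal_animals, reference_populations))
  conv <- logical(length(rows))
  iters <- integer(length(rows))
  for (a in seq_along(rows)) {
    x <- X[rows[a], ]
    ok <- !is.na(x)
    xa <- x[ok]; f <- Fm[ok, , drop = FALSE]
    q <- rep(1 / K, K)
    it <- 0L
    repeat {
      it <- it + 1L
      num1 <- sweep(f, 2, q, "*")              # allele-1 responsibilities
      den1 <- rowSums(num1)
      num0 <- sweep(1 - f, 2, q, "*")
      den0 <- rowSums(num0)
      expected <- colSums(num1 * (xa / den1)) +
        colSums(num0 * ((2 - xa) / den0))
      q_new <- expected / (2 * length(xa))
      delta <- max(abs(q_new - q))
      q <- q_new
      if (delta < tol) { conv[a] <- TRUE; break }
      if (it >= max_iter) break
    }
    Q[a, ] <- q
    iters[a] <- it
  }
  attr(Q, "converged") <- conv
  attr(Q, "iterations") <- iters
  attr(Q, "degenerate") <- degenerate
  Q
}

#' Staged selection of a most-unrelated purebred nucleus
#'
#' Deterministic three-stage exclusion among the focal-breed animals:
#' \enumerate{
#'   \item animals whose pedigree foreign fraction exceeds `max_foreign`;
#'   \item while any remaining pair has a relationship above `max_rel`,
#'     one member of the worst pair is excluded: preferentially an inbred
#'     one (self-relationship above `max_self`), otherwise the one with
#'     the higher mean relationship to the remaining focal animals, ties
#'     broken by lexicographic id;
#'   \item animals whose mean relationship to any reference breed exceeds
#'     that breed's mean plus `sd_mult` standard deviations, both taken
#'     over all focal animals.
#' }
#'
#' @param G relationship matrix over all animals (dimnames = ids).
#' @param populations named population label per animal in `G`.
#' @param focal focal breed label.
#' @param foreign_fraction named per-focal-animal pedigree foreign
#'   fraction (1 minus focal-breed fraction).
#' @param thresholds list with `max_foreign`, `max_rel`, `max_self`,
#'   `sd_mult`.
#' @return list of class `selection_report`: `report` (per-animal
#'   data.frame with values, flags, exclusion stage and reason) and
#'   `nucleus` (retained animal ids).
#' @export
select_nucleus <- function(G, populations, focal, foreign_fraction,
                           thresholds = list(max_foreign = 0.125,
                                             max_rel = 0.25,
                                             max_self = 1.05,
                                             sd_mult = 2)) {
  ids <- rownames(G)
  focal_ids <- ids[populations[ids] == focal]
  if (length(focal_ids) == 0) stop("empty focal set")
  ref_breeds <- setdiff(unique(populations[ids]), focal)
  ff <- foreign_fraction[focal_ids]
  ff[is.na(ff)] <- 0
  self_rel <- diag(G)[focal_ids]

  status <- stats::setNames(rep("nucleus", length(focal_ids)), focal_ids)
  stage <- stats::setNames(rep(NA_integer_, length(focal_ids)), focal_ids)
  reason <- stats::setNames(rep("", length(focal_ids)), focal_ids)

  ## stage 1: pedigree admixture
  out1 <- focal_ids[ff > thresholds$max_foreign]
  status[out1] <- "excluded"
  stage[out1] <- 1L
  reason[out1] <- sprintf("pedigree foreign fraction %.3f > %.3f",
                          ff[out1], thresholds$max_foreign)

  ## stage 2: pairwise relationships
  remaining <- focal_ids[status == "nucleus"]
  repeat {
    if (length(remaining) < 2) break
    sub <- G[remaining, remaining, drop = FALSE]
    diag(sub) <- -Inf
    mx <- max(sub)
    if (mx <= thresholds$max_rel) break
    w <- which(sub == mx, arr.ind = TRUE)[1, ]
    pair <- sort(remaining[w])
    inbred <- self_rel[pair] > thresholds$max_self
    if (sum(inbred) == 1) {
      drop_id <- pair[inbred]
      why <- sprintf("relationship %.3f > %.3f; inbred member (self %.3f)",
                     mx, thresholds$max_rel, self_rel[pair[inbred]])
    } else {
      mr <- vapply(pair, function(a)
        mean(G[a, setdiff(remaining, a)]), numeric(1))
      drop_id <- pair[order(-mr, pair)][1]
      why <- sprintf("relationship %.3f > %.3f; higher mean relationship",
                     mx, thresholds$max_rel)
    }
    status[drop_id] <- "excluded"
    stage[drop_id] <- 2L
    reason[drop_id] <- why
    remaining <- setdiff(remaining, drop_id)
  }

  ## stage 3: cross-breed relatedness (baseline over all focal animals)
  mean_rel <- matrix(NA_real_, length(focal_ids), length(ref_breeds),
                     dimnames = list(focal_ids, ref_breeds))
  for (b in ref_breeds) {
    members <- ids[populations[ids] == b]
    mean_rel[, b] <- vapply(focal_ids, function(a)
      mean(G[a, setdiff(members, a)]), numeric(1))
    thr <- mean(mean_rel[, b]) + thresholds$sd_mult * stats::sd(mean_rel[, b])
    flag <- remaining[mean_rel[remaining, b] > thr]
    if (length(flag)) {
      status[flag] <- "excluded"
      stage[flag] <- 3L
      reason[flag] <- sprintf("mean relationship to %s %.3f > %.3f", b,
                              mean_rel[flag, b], thr)
      remaining <- setdiff(remaining, flag)
    }
  }

  max_pair <- vapply(focal_ids, function(a)
    max(G[a, setdiff(focal_ids, a)]), numeric(1))
  report <- data.frame(animal_id = focal_ids,
                       foreign_fraction = as.numeric(ff),
                       self_rel = as.numeric(self_rel),
                       max_rel_focal = max_pair,
                       status = as.character(status),
                       stage = as.integer(stage),
                       reason = as.character(reason),
                       stringsAsFactors = FALSE)
  report <- cbind(report, as.data.frame(mean_rel))
  structure(list(report = report, nucleus = remaining,
                 thresholds = thresholds), class = "selection_report")
}

#' Correlations among admixture evidence sources
#'
#' Pearson correlations among the numeric type class (focal = 0, semi = 1,
#' source = 2), the pedigree source-breed fraction, the mean genomic
#' relationship to the source breed, and the estimated source admixture
#' fraction.  A constant column yields `NA` correlations (undefined, not
#' zero).
#'
#' @param type character vector of type classes per animal.
#' @param pedigree_fraction pedigree source-breed fraction per animal.
#' @param mean_rel_source mean genomic relationship to the source breed.
#' @param admixture_fraction estimated source admixture fraction.
#' @return 4 x 4 correlation matrix.
#' @export
correlate_evidence <- function(type, pedigree_fraction, mean_rel_source,
                               admixture_fraction) {
  if (length(type) < 3) stop("at least three animals required")
  tnum <- c(focal = 0, semi = 1, source = 2)[type]
  dat <- cbind(type = as.numeric(tnum),
               pedigree = pedigree_fraction,
               mean_rel = mean_rel_source,
               admixture = admixture_fraction)
  suppressWarnings(stats::cor(dat, use = "pairwise.complete.obs"))
}
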