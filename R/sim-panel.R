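#' Configuration for the synthetic multi-breed SNP panel generator
#'
#' Bundles all parameters of [simulate_panel()].  The defaults emulate a
#' medium-density SNP-array survey of 15 European cattle breeds: unequal
#' sample sizes (20-80 animals per breed), 29 autosomes at ~56 kb mean
#' marker spacing, moderate breed divergence, and a focal breed carrying a
#' documented history of introgression from one source breed.
#'
#' Breed divergence is parameterised per breed by a drift coefficient
#' `F` in (0,1): haplotype-pool frequencies of each breed are drawn around
#' the ancestral pool frequencies with a Dirichlet concentration of
#' `(1-F)/F`, the multi-allelic analogue of the Balding-Nichols
#' beta construction used for single SNPs.
#'
#' @param n_breeds number of breeds.
#' @param animals_per_breed integer vector of length `n_breeds`.
#' @param breed_names character vector of breed labels.
#' @param n_chromosomes number of autosomes.
#' @param snps_per_chromosome SNPs simulated per autosome.
#' @param mean_spacing_bp mean inter-marker distance in bp (exponential gaps).
#' @param breed_drift per-breed drift coefficient F, each in (0,1).
#' @param focal_breed label of the admixed focal breed.
#' @param admixture_spec data.frame with columns `fraction` (share of focal
#'   animals), `source` (source breed label) and `q` (admixture proportion
#'   in `[0,1]`).  Remaining focal animals are purebred.
#' @param pool_size founder haplotypes per 4-SNP block pool (at most 16).
#' @param missing_rate per-genotype missingness probability.
#' @param type_noise probability that an animal's type class is misrecorded.
#' @param seed integer RNG seed; the whole simulation is reproducible from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_breeds = 15,
                       animals_per_breed = c(50, 49, 50, 46, 50, 35, 50, 76,
                                             30, 24, 22, 21, 24, 43, 37),
                       breed_names = sprintf("B%02d", seq_len(n_breeds)),
                       n_chromosomes = 29,
                       snps_per_chromosome = 1534,
                       mean_spacing_bp = 56400,
                       breed_drift = rep(0.1, n_breeds),
                       focal_breed = breed_names[8],
                       admixture_spec = data.frame(
                         fraction = c(6, 12, 12) / 76,
                         source = breed_names[7],
                         q = c(0.0625, 0.25, 0.5)),
                       pool_size = 6,
                       missing_rate = 0.02,
                       type_noise = 0.1,
                       seed = 1L) {
  stopifnot(length(animals_per_breed) == n_breeds,
            length(breed_names) == n_breeds,
            length(breed_drift) == n_breeds)
  if (any(breed_drift <= 0 | breed_drift >= 1))
    stop("breed_drift values must lie strictly in (0, 1)")
  if (missing_rate < 0 || missing_rate > 1 || type_noise < 0 || type_noise > 1)
    stop("missing_rate and type_noise must be probabilities in [0, 1]")
  if (!focal_breed %in% breed_names) stop("unknown focal_breed")
  if (nrow(admixture_spec) > 0) {
    if (any(admixture_spec$q < 0 | admixture_spec$q > 1))
      stop("admixture proportions q must lie in [0, 1]")
    if (any(!admixture_spec$source %in% breed_names))
      stop("unknown source breed in admixture_spec")
    if (sum(admixture_spec$fraction) > 1 + 1e-12)
      stop("admixture_spec fractions exceed the focal sample")
  }
  if (pool_size < 2 || pool_size > 16) stop("pool_size must be in 2..16")
  cfg <- list(n_breeds = n_breeds, animals_per_breed = animals_per_breed,
              breed_names = breed_names, n_chromosomes = n_chromosomes,
              snps_per_chromosome = snps_per_chromosome,
              mean_spacing_bp = mean_spacing_bp, breed_drift = breed_drift,
              focal_breed = focal_breed, admixture_spec = admixture_spec,
              pool_size = pool_size, missing_rate = missing_rate,
              type_noise = type_noise, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Draw `k` distinct binary haplotypes of length `len` whose per-site allele-1
# probabilities are `p`.  Falls back to enumeration when 2^len is small.
.draw_pool <- function(k, p) {
  len <- length(p)
  k <- min(k, 2^len)
  seen <- character(0)
  pool <- matrix(0L, nrow = k, ncol = len)
  i <- 1L
  tries <- 0L
  while (i <= k) {
    h <- as.integer(stats::runif(len) < p)
    key <- paste(h, collapse = "")
    if (!key %in% seen) {
      pool[i, ] <- h
      seen <- c(seen, key)
      i <- i + 1L
    }
    tries <- tries + 1L
    if (tries > 200L * k) {  # near-monomorphic sites: enumerate instead
      all_h <- as.matrix(expand.grid(rep(list(0:1), len)))
      ord <- sample.int(nrow(all_h))
      pool <- all_h[ord[seq_len(k)], , drop = FALSE]
      storage.mode(pool) <- "integer"
      break
    }
  }
  pool
}

.rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-8))
  if (all(x == 0)) x[sample.int(length(x), 1)] <- 1
  x / sum(x)
}

#' Simulate a phased multi-breed SNP panel with known ground truth
#'
#' Generates SNP positions (exponential inter-marker gaps), ancestral allele
#' frequencies `Uniform(0.05, 0.95)`, and per-block founder haplotype pools.
#' Consecutive 4-SNP groups form generator blocks; each block has
#' `pool_size` distinct founder haplotypes with ancestral Dirichlet
#' frequencies, and each breed's pool frequencies are drawn with Dirichlet
#' concentration `(1-F)/F` around the ancestral ones (Balding-Nichols style
#' drift).  Blocks are in linkage equilibrium with respect to each other.
#' Admixed focal-breed animals draw each block haplotype's breed of origin
#' i.i.d. with probability `q` from the source breed.
#'
#' Type classes follow the true focal-ancestry fraction (pure at >= 7/8,
#' semi at >= 1/2, otherwise source type) and are misrecorded with
#' probability `type_noise`.  The pedigree has three strata: known-pedigree
#' purebreds (focal founders), known-pedigree admixed animals (F1 and
#' backcross structures for q >= 0.25), and no-pedigree animals recorded as
#' purebred focal.  Genotypes are masked at `missing_rate`; the unmasked
#' phased truth is kept in the ground-truth component.
#'
#' @param config a [sim_config()] object.
#' @return list with components `panel` (SNP map data.frame), `haplotypes`
#'   (phased haplotype object: `animal_id`, `population`, matrices `H1`,
#'   `H2`), `pedigree`, `types`, and `truth` (ancestry fractions, per-block
#'   haplotype origins, intended q, unmasked haplotypes).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  ## --- SNP map -------------------------------------------------------------
  chroms <- integer(0); pos <- integer(0)
  for (ch in seq_len(cfg$n_chromosomes)) {
    gaps <- pmax(1, round(stats::rexp(cfg$snps_per_chromosome,
                                      rate = 1 / cfg$mean_spacing_bp)))
    p <- cumsum(gaps)
    chroms <- c(chroms, rep(ch, length(p)))
    pos <- c(pos, p)
  }
  m <- length(pos)
  panel <- data.frame(chrom = as.character(chroms), pos = as.integer(pos),
                      snp_id = sprintf("snp%06d", seq_len(m)),
                      ref = "A", alt = "B", stringsAsFactors = FALSE)
  p_anc <- stats::runif(m, 0.05, 0.95)

  ## --- animals -------------------------------------------------------------
  pops <- rep(cfg$breed_names, cfg$animals_per_breed)
  n <- length(pops)
  ids <- sprintf("%s_%03d", pops, unlist(lapply(cfg$animals_per_breed, seq_len)))
  focal_idx <- which(pops == cfg$focal_breed)

  ## intended admixture per focal animal
  q_intended <- rep(0, n)
  q_source <- rep(NA_character_, n)
  if (nrow(cfg$admixture_spec) > 0) {
    n_focal <- length(focal_idx)
    counts <- round(cfg$admixture_spec$fraction * n_focal)
    pick_from <- focal_idx
    for (r in seq_len(nrow(cfg$admixture_spec))) {
      k <- min(counts[r], length(pick_from))
      if (k == 0) next
      chosen <- pick_from[seq_len(k)]  # deterministic: first unassigned
      pick_from <- setdiff(pick_from, chosen)
      q_intended[chosen] <- cfg$admixture_spec$q[r]
      q_source[chosen] <- cfg$admixture_spec$source[r]
    }
  }

  ## --- generator blocks and haplotype pools --------------------------------
  blk_id <- integer(m)
  nb <- 0L
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    grp <- (seq_along(idx) - 1L) %/% 4L
    blk_id[idx] <- grp + nb + 1L
    nb <- nb + max(grp) + 1L
  }
  block_members <- split(seq_len(m), blk_id)

  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  origin1 <- matrix(NA_integer_, n, length(block_members))
  origin2 <- matrix(NA_integer_, n, length(block_members))
  breed_of <- match(pops, cfg$breed_names)

  for (b in seq_along(block_members)) {
    snps <- block_members[[b]]
    pool <- .draw_pool(cfg$pool_size, p_anc[snps])
    K <- nrow(pool)
    pi_anc <- .rdirichlet1(rep(1, K))
    freqs <- matrix(0, cfg$n_breeds, K)
    for (br in seq_len(cfg$n_breeds)) {
      Fst <- cfg$breed_drift[br]
      freqs[br, ] <- .rdirichlet1(pi_anc * (1 - Fst) / Fst)
    }
    src <- match(q_source, cfg$breed_names)
    for (hap in 1:2) {
      org <- breed_of
      adm <- which(q_intended > 0)
      if (length(adm)) {
        from_src <- stats::runif(length(adm)) < q_intended[adm]
        org[adm[from_src]] <- src[adm[from_src]]
      }
      draw <- vapply(org, function(o) sample.int(K, 1, prob = freqs[o, ]), 1L)
      if (hap == 1) {
        H1[, snps] <- pool[draw, , drop = FALSE]
        origin1[, b] <- org
      } else {
        H2[, snps] <- pool[draw, , drop = FALSE]
        origin2[, b] <- org
      }
    }
  }

  ## --- ground truth before masking ----------------------------------------
  anc <- matrix(0, n, cfg$n_breeds, dimnames = list(ids, cfg$breed_names))
  for (br in seq_len(cfg$n_breeds))
    anc[, br] <- (rowSums(origin1 == br) + rowSums(origin2 == br)) /
      (2 * ncol(origin1))
  truth_H1 <- H1; truth_H2 <- H2

  ## --- missingness (per animal x SNP genotype, both haplotypes) ------------
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < cfg$missing_rate, n, m)
    H1[mask] <- NA_integer_
    H2[mask] <- NA_integer_
  }

  ## --- type classes (focal animals) ----------------------------------------
  focal_anc <- anc[, cfg$focal_breed]
  type_true <- ifelse(focal_anc >= 7 / 8, "focal",
                      ifelse(focal_anc >= 1 / 2, "semi", "source"))
  type_rec <- type_true
  flip <- stats::runif(n) < cfg$type_noise
  lev <- c("focal", "semi", "source")
  for (i in which(flip))
    type_rec[i] <- sample(setdiff(lev, type_true[i]), 1)
  types <- data.frame(animal_id = ids[focal_idx],
                      type = type_rec[focal_idx], stringsAsFactors = FALSE)

  ## --- pedigree -------------------------------------------------------------
  ped <- data.frame(id = character(0), sire = character(0),
                    dam = character(0), breed = character(0),
                    stringsAsFactors = FALSE)
  extra <- list()
  rows <- list()
  for (i in seq_len(n)) {
    if (!(i %in% focal_idx)) {
      rows[[length(rows) + 1]] <- c(ids[i], NA, NA, pops[i])
    } else if (q_intended[i] >= 0.5) {           # F1: known parents
      s <- paste0(ids[i], "_sire"); d <- paste0(ids[i], "_dam")
      extra[[length(extra) + 1]] <- c(s, NA, NA, q_source[i])
      extra[[length(extra) + 1]] <- c(d, NA, NA, cfg$focal_breed)
      rows[[length(rows) + 1]] <- c(ids[i], s, d, NA)
    } else if (q_intended[i] >= 0.25) {          # BC1: F1 sire x focal dam
      s <- paste0(ids[i], "_sire"); d <- paste0(ids[i], "_dam")
      gs <- paste0(s, "_s"); gd <- paste0(s, "_d")
      extra[[length(extra) + 1]] <- c(gs, NA, NA, q_source[i])
      extra[[length(extra) + 1]] <- c(gd, NA, NA, cfg$focal_breed)
      extra[[length(extra) + 1]] <- c(s, gs, gd, NA)
      extra[[length(extra) + 1]] <- c(d, NA, NA, cfg$focal_breed)
      rows[[length(rows) + 1]] <- c(ids[i], s, d, NA)
    } else if (q_intended[i] > 0) {              # low-grade admixed, no pedigree
      rows[[length(rows) + 1]] <- c(ids[i], NA, NA, NA)
    } else if (i %% 4 == 0) {                    # some purebreds lack records
      rows[[length(rows) + 1]] <- c(ids[i], NA, NA, NA)
    } else {                                     # purebred focal founder
      rows[[length(rows) + 1]] <- c(ids[i], NA, NA, cfg$focal_breed)
    }
  }
  all_rows <- do.call(rbind, c(extra, rows))
  ped <- data.frame(id = all_rows[, 1], sire = all_rows[, 2],
                    dam = all_rows[, 3], breed = all_rows[, 4],
                    stringsAsFactors = FALSE)

  haps <- list(animal_id = ids, population = pops, H1 = H1, H2 = H2)
  class(haps) <- "phased_haps"
  truth <- list(ancestry = anc,
                q_intended = stats::setNames(q_intended, ids),
                q_source = stats::setNames(q_source, ids),
                origin1 = origin1, origin2 = origin2,
                type_true = stats::setNames(type_true, ids),
                H1 = truth_H1, H2 = truth_H2)
  list(panel = panel, haplotypes = haps, pedigree = ped,
       types = types, truth = truth)
}

#' Write simulation artifacts to plain-text files
#'
#' Writes the phased VCF, tab-delimited SNP map, pedigree CSV, type-class
#' CSV and ground-truth JSON for a [simulate_panel()] result.
#'
#' @param sim result of [simulate_panel()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of file paths written.
#' @export
write_sim <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "panel.vcf"),
             map = file.path(dir, "snp_map.tsv"),
             ped = file.path(dir, "pedigree.csv"),
             types = file.path(dir, "types.csv"),
             truth = file.path(dir, "ground_truth.json"))
  write_phased_vcf(sim$panel, sim$haplotypes, paths["vcf"])
  utils::write.table(sim$panel[, c("chrom", "pos", "snp_id")], paths["map"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(sim$pedigree, paths["ped"], row.names = FALSE, na = "")
  utils::write.csv(sim$types, paths["types"], row.names = FALSE)
  tr <- sim$truth
  jsonlite::write_json(
    list(ancestry = as.data.frame(tr$ancestry),
         animal_id = rownames(tr$ancestry),
         q_intended = tr$q_intended, q_source = tr$q_source,
         type_true = tr$type_true),
    paths["truth"], auto_unbox = FALSE, digits = NA, na = "null")
  invisible(paths)
}
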