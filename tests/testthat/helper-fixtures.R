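# Build a phased-haplotype object directly from two allele matrices.
make_haps <- function(H1, H2, pops, ids = sprintf("a%02d", seq_len(nrow(H1)))) {
  structure(list(animal_id = ids, population = pops,
                 H1 = H1, H2 = H2), class = "phased_haps")
}

# Build a block_alleles object directly from two code matrices; codes are
# densified to 0..K-1 per block as encode_block_alleles() guarantees.
make_ba <- function(A1, A2, pops, ids = sprintf("a%02d", seq_len(nrow(A1)))) {
  codes <- vector("list", ncol(A1))
  for (b in seq_len(ncol(A1))) {
    lev <- sort(unique(c(A1[, b], A2[, b])))
    lev <- lev[!is.na(lev)]
    A1[, b] <- match(A1[, b], lev) - 1L
    A2[, b] <- match(A2[, b], lev) - 1L
    codes[[b]] <- stats::setNames(seq_along(lev) - 1L, paste0("h", lev))
  }
  structure(list(animal_id = ids, population = pops,
                 A1 = A1, A2 = A2, codes = codes, blocks = NULL),
            class = "block_alleles")
}

# Random multi-population block-allele data: each population's allele
# frequencies drawn from a Dirichlet around common frequencies.  `drift`
# may be a vector (one divergence level per population).
random_ba <- function(n_per_pop, n_blocks, n_alleles = 6, drift = 0.2,
                      seed = 1) {
  set.seed(seed)
  npop <- length(n_per_pop)
  drift <- rep_len(drift, npop)
  pops <- rep(paste0("P", seq_len(npop)), n_per_pop)
  n <- length(pops)
  A1 <- matrix(NA_integer_, n, n_blocks)
  A2 <- matrix(NA_integer_, n, n_blocks)
  for (b in seq_len(n_blocks)) {
    base <- rgamma(n_alleles, 1); base <- base / sum(base)
    for (p in seq_len(npop)) {
      f <- rgamma(n_alleles, base * (1 - drift[p]) / drift[p])
      f <- f / sum(f)
      rows <- which(pops == paste0("P", p))
      A1[rows, b] <- sample.int(n_alleles, length(rows), TRUE, f) - 1L
      A2[rows, b] <- sample.int(n_alleles, length(rows), TRUE, f) - 1L
    }
  }
  make_ba(A1, A2, pops)
}

# Small simulated panel for end-to-end tests.
small_sim <- function(seed = 7, n_snps = 300, spacing = 20000,
                      drift = 0.15, breeds = 3) {
  cfg <- sim_config(
    n_breeds = breeds,
    animals_per_breed = rep(20, breeds),
    breed_names = paste0("P", seq_len(breeds)),
    n_chromosomes = 2, snps_per_chromosome = n_snps %/% 2,
    mean_spacing_bp = spacing,
    breed_drift = rep(drift, breeds),
    focal_breed = paste0("P", breeds),
    admixture_spec = data.frame(fraction = numeric(0), source = character(0),
                                q = numeric(0)),
    missing_rate = 0, type_noise = 0, seed = seed)
  simulate_panel(cfg)
}
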