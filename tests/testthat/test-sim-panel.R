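test_that("the generator is reproducible and validates its inputs", {
  s1 <- small_sim(seed = 3)
  s2 <- small_sim(seed = 3)
  expect_identical(s1$haplotypes$H1, s2$haplotypes$H1)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$truth$ancestry, s2$truth$ancestry)
  s3 <- small_sim(seed = 4)
  expect_false(identical(s1$haplotypes$H1, s3$haplotypes$H1))

  expect_error(sim_config(breed_drift = rep(1.2, 15)), "strictly in")
  expect_error(sim_config(missing_rate = 2), "probabilities")
  expect_error(sim_config(admixture_spec = data.frame(
    fraction = 0.1, source = "B01", q = 1.5)), "q must lie")
  expect_error(sim_config(n_breeds = 3), "length")
})

test_that("positions increase within chromosome and missingness is paired", {
  cfg <- sim_config(n_breeds = 2, animals_per_breed = c(10, 10),
                    breed_names = c("A", "B"), n_chromosomes = 3,
                    snps_per_chromosome = 50, breed_drift = c(0.1, 0.1),
                    focal_breed = "B",
                    admixture_spec = data.frame(fraction = numeric(0),
                                                source = character(0),
                                                q = numeric(0)),
                    missing_rate = 0.1, seed = 8)
  sim <- simulate_panel(cfg)
  for (ch in unique(sim$panel$chrom)) {
    p <- sim$panel$pos[sim$panel$chrom == ch]
    expect_true(all(diff(p) > 0))
  }
  expect_identical(is.na(sim$haplotypes$H1), is.na(sim$haplotypes$H2))
  expect_gt(mean(is.na(sim$haplotypes$H1)), 0.05)
  # masked truth is kept unmasked
  expect_false(anyNA(sim$truth$H1))
})

test_that("planted admixture appears in the ground truth as specified", {
  cfg <- sim_config(n_breeds = 2, animals_per_breed = c(10, 12),
                    breed_names = c("S", "C"), n_chromosomes = 1,
                    snps_per_chromosome = 200, breed_drift = c(0.2, 0.2),
                    focal_breed = "C",
                    admixture_spec = data.frame(fraction = c(1 / 12, 2 / 12),
                                                source = "S", q = c(1, 0.5)),
                    missing_rate = 0, seed = 12)
  sim <- simulate_panel(cfg)
  q1 <- names(which(sim$truth$q_intended == 1))
  expect_identical(length(q1), 1L)
  # q = 1: every block haplotype originates from the source breed
  expect_equal(unname(sim$truth$ancestry[q1, "S"]), 1)
  q5 <- names(which(sim$truth$q_intended == 0.5))
  expect_true(all(abs(sim$truth$ancestry[q5, "S"] - 0.5) < 0.25))
  # ancestry fractions always sum to one
  expect_true(all(abs(rowSums(sim$truth$ancestry) - 1) < 1e-12))
  # type classes reflect ancestry (no noise configured in this fixture)
  tt <- sim$truth$type_true
  expect_identical(unname(tt[q1]), "source")
  # pedigree strata: q=0.5 animals have recorded F1 parents
  ped <- sim$pedigree
  f1_row <- ped[ped$id == q5[1], ]
  expect_false(is.na(f1_row$sire))
  sire_row <- ped[ped$id == f1_row$sire, ]
  expect_identical(sire_row$breed, "S")
})

test_that("no divergence means no differentiation between breeds", {
  cfg <- sim_config(n_breeds = 2, animals_per_breed = c(25, 25),
                    breed_names = c("A", "B"), n_chromosomes = 2,
                    snps_per_chromosome = 200, mean_spacing_bp = 20000,
                    breed_drift = c(0.001, 0.001), focal_breed = "B",
                    admixture_spec = data.frame(fraction = numeric(0),
                                                source = character(0),
                                                q = numeric(0)),
                    missing_rate = 0, seed = 31)
  sim <- simulate_panel(cfg)
  ba <- encode_block_alleles(sim$haplotypes, build_blocks(sim$panel))
  dest <- dest_pairwise(tally_alleles(ba))["A", "B"]
  expect_lt(abs(dest), 0.02)
})

test_that("admixed animals are genomically closer to the source breed", {
  cfg <- sim_config(n_breeds = 2, animals_per_breed = c(20, 22),
                    breed_names = c("S", "C"), n_chromosomes = 2,
                    snps_per_chromosome = 500, breed_drift = c(0.15, 0.15),
                    focal_breed = "C",
                    admixture_spec = data.frame(fraction = 2 / 22,
                                                source = "S", q = 0.5),
                    missing_rate = 0, seed = 77)
  sim <- simulate_panel(cfg)
  G <- genomic_relationship(sim$haplotypes)
  src <- sim$haplotypes$animal_id[sim$haplotypes$population == "S"]
  adm <- names(which(sim$truth$q_intended == 0.5))
  pure <- setdiff(sim$haplotypes$animal_id[sim$haplotypes$population == "C"],
                  adm)
  rel_adm <- mean(sapply(adm, mean_relationship_to_population, G = G,
                         members = src))
  rel_pure <- mean(sapply(pure, mean_relationship_to_population, G = G,
                          members = src))
  expect_gt(rel_adm, rel_pure)
})

test_that("simulation artifacts are written as parseable plain text", {
  sim <- small_sim(seed = 15, n_snps = 40)
  dir <- tempfile()
  paths <- write_sim(sim, dir)
  expect_true(all(file.exists(paths)))
  rt <- read_phased_vcf(paths["vcf"])
  expect_identical(dim(rt$haplotypes$H1), dim(sim$haplotypes$H1))
  truth <- jsonlite::read_json(paths["truth"])
  expect_identical(length(truth$animal_id), length(sim$haplotypes$animal_id))
})
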