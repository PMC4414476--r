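ped_fixture <- function() {
  data.frame(
    id   = c("srcF", "focF1", "focF2", "f1", "bc1", "nop"),
    sire = c(NA, NA, NA, "srcF", "f1", NA),
    dam  = c(NA, NA, NA, "focF1", "focF2", NA),
    breed = c("SRC", "FOC", "FOC", NA, NA, NA),
    stringsAsFactors = FALSE)
}

test_that("pedigree breed composition averages parental fractions", {
  comp <- pedigree_breed_composition(ped_fixture(), focal = "FOC")
  expect_equal(comp$fractions["f1", "SRC"], 0.5)     # F1
  expect_equal(comp$fractions["bc1", "SRC"], 0.25)   # BC1
  expect_equal(comp$fractions["nop", "FOC"], 1)      # unknown both parents
  expect_true(comp$incomplete["nop"])
  expect_false(comp$incomplete["f1"])
  expect_true(all(abs(rowSums(comp$fractions) - 1) < 1e-12))

  cyc <- data.frame(id = c("a", "b"), sire = c("b", "a"), dam = c(NA, NA),
                    breed = c(NA, NA), stringsAsFactors = FALSE)
  expect_error(pedigree_breed_composition(cyc, "FOC"), "cycle")
})

test_that("an unknown parent contributes focal ancestry with a flag", {
  ped <- data.frame(id = c("srcF", "half"), sire = c(NA, "srcF"),
                    dam = c(NA, "ghost"), breed = c("SRC", NA),
                    stringsAsFactors = FALSE)
  comp <- pedigree_breed_composition(ped, "FOC")
  expect_equal(comp$fractions["half", "SRC"], 0.5)
  expect_equal(comp$fractions["half", "FOC"], 0.5)
  expect_true(comp$incomplete["half"])
})

test_that("supervised admixture recovers pure and mixed ancestries", {
  cfg <- sim_config(n_breeds = 2, animals_per_breed = c(50, 51),
                    breed_names = c("R1", "R2"), n_chromosomes = 2,
                    snps_per_chromosome = 1000, mean_spacing_bp = 20000,
                    breed_drift = c(0.2, 0.2), focal_breed = "R2",
                    admixture_spec = data.frame(fraction = 1 / 51,
                                                source = "R1", q = 0.5),
                    missing_rate = 0, type_noise = 0, seed = 101)
  sim <- simulate_panel(cfg)
  pops <- sim$haplotypes$population
  adm_id <- names(which(sim$truth$q_intended == 0.5))
  pure_id <- setdiff(sim$haplotypes$animal_id[pops == "R2"], adm_id)[1]
  # keep the query animals out of the reference frequency pools
  haps <- sim$haplotypes
  haps$population[haps$animal_id %in% c(adm_id, pure_id)] <- "query"
  Q <- supervised_admixture(haps, c("R1", "R2"), c(pure_id, adm_id))
  expect_true(all(abs(rowSums(Q) - 1) < 1e-8))
  expect_gte(Q[pure_id, "R2"], 0.95)
  expect_equal(unname(Q[adm_id, "R1"]),
               unname(sim$truth$ancestry[adm_id, "R1"]), tolerance = 0.08)
  expect_true(all(attr(Q, "converged")))
})

test_that("identical reference populations are reported as degenerate", {
  H1 <- matrix(rep(c(0L, 1L), 10), 4, 5)
  haps <- make_haps(H1, H1, c("R1", "R1", "R2", "R2"))
  expect_warning(Q <- supervised_admixture(haps, c("R1", "R2"), "a01"),
                 "indistinguishable")
  expect_true(attr(Q, "degenerate"))
})

test_that("nucleus selection stages fire in order with logged reasons", {
  ids <- c(paste0("f", 1:6), "r1", "r2")
  pops <- stats::setNames(c(rep("FOC", 6), "REF", "REF"), ids)
  G <- diag(1, 8); dimnames(G) <- list(ids, ids)
  G["f1", "f2"] <- G["f2", "f1"] <- 0.30          # violating pair
  G["f2", "f2"] <- 1.10                           # f2 is inbred
  ff <- stats::setNames(c(0, 0, 0.14, 0, 0, 0), paste0("f", 1:6))
  sel <- select_nucleus(G, pops, "FOC", ff)
  rep_df <- sel$report
  expect_identical(rep_df$stage[rep_df$animal_id == "f3"], 1L)   # pedigree
  expect_identical(rep_df$stage[rep_df$animal_id == "f2"], 2L)   # inbred member
  expect_match(rep_df$reason[rep_df$animal_id == "f2"], "inbred")
  expect_true("f1" %in% sel$nucleus)
  expect_identical(sort(sel$nucleus), c("f1", "f4", "f5", "f6"))

  # no violations: every focal animal is retained
  G0 <- diag(1, 8); dimnames(G0) <- dimnames(G)
  sel0 <- select_nucleus(G0, pops, "FOC",
                         stats::setNames(rep(0, 6), paste0("f", 1:6)))
  expect_identical(sort(sel0$nucleus), sort(paste0("f", 1:6)))

  # determinism
  sel2 <- select_nucleus(G, pops, "FOC", ff)
  expect_identical(sel$report, sel2$report)
  expect_error(select_nucleus(G, stats::setNames(rep("REF", 8), ids),
                              "FOC", ff), "empty focal")
})

test_that("tightening the relationship threshold never grows the nucleus", {
  set.seed(47)
  n <- 20
  ids <- c(sprintf("f%02d", 1:15), sprintf("r%02d", 1:5))
  pops <- stats::setNames(c(rep("FOC", 15), rep("REF", 5)), ids)
  W <- matrix(rnorm(n * 40), n, 40)
  G <- tcrossprod(W) / 40
  dimnames(G) <- list(ids, ids)
  ff <- stats::setNames(rep(0, 15), ids[1:15])
  sizes <- sapply(c(2, 1, 0.5, 0.25, 0.1), function(mr)
    length(select_nucleus(G, pops, "FOC", ff,
                          list(max_foreign = 0.125, max_rel = mr,
                               max_self = 1e9, sd_mult = 1e9))$nucleus))
  expect_true(all(diff(sizes) <= 0))
})

test_that("evidence correlations handle perfect and undefined cases", {
  typ <- c("focal", "semi", "source", "focal")
  x <- c(0, 1, 2, 0)
  cm <- correlate_evidence(typ, x, -x, x)
  expect_equal(cm["type", "pedigree"], 1)
  expect_equal(cm["type", "mean_rel"], -1)
  cm2 <- correlate_evidence(typ, rep(0.5, 4), x, x)
  expect_true(is.na(cm2["type", "pedigree"]))
  expect_error(correlate_evidence("focal", 1, 1, 1), "three")
})
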