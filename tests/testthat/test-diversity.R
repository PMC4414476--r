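test_that("allele tallies match hand counts and ignore absent genotypes", {
  A1 <- cbind(c(0L, 0L, 1L, NA), c(0L, 1L, 1L, 0L))
  A2 <- cbind(c(0L, 1L, 1L, NA), c(0L, 1L, 2L, 0L))
  ba <- make_ba(A1, A2, c("X", "X", "Y", "Y"))
  ac <- tally_alleles(ba)
  expect_identical(unname(ac$counts[[1]]["X", ]), c(3L, 1L))
  expect_identical(unname(ac$counts[[1]]["Y", ]), c(0L, 2L))
  expect_identical(unname(ac$n_typed[, 1]), c(2L, 1L))   # one animal absent
  expect_error(tally_alleles(ba, c("X", NA, "Y", "Y")), "unknown population")
})

test_that("alleles partition into private, rare and common classes", {
  # 3 pops, 1 block: allele 0 in all, allele 1 only in X, allele 2 in X+Y
  A1 <- cbind(c(0L, 1L, 0L, 2L, 0L, 0L))
  A2 <- cbind(c(1L, 2L, 0L, 0L, 0L, 0L))
  ba <- make_ba(A1, A2, c("X", "X", "Y", "Y", "Z", "Z"))
  part <- partition_alleles(tally_alleles(ba))
  expect_identical(unname(part$npA[c("X", "Y", "Z")]), c(1, 0, 0))
  expect_identical(unname(part$nrA[c("X", "Y", "Z")]), c(1, 1, 0))
  expect_identical(part$ncA, 1L)
  expect_identical(part$nrA_distinct, 1L)
  # classes are exhaustive and mutually exclusive per observed allele
  expect_identical(part$nA_all,
                   part$ncA + part$nrA_distinct + as.integer(sum(part$npA)))
})

test_that("heterozygosity follows Nei's unbiased formula", {
  # four animals all heterozygous A/B: counts {A:4, B:4}
  A1 <- cbind(rep(0L, 4)); A2 <- cbind(rep(1L, 4))
  ba <- make_ba(A1, A2, rep("X", 4))
  h <- heterozygosity(ba)
  expect_equal(h$H_O, 1)
  expect_equal(h$H_E, (8 / 7) * 0.5, tolerance = 1e-12)  # 0.5714286

  # all homozygous identical
  ba0 <- make_ba(cbind(rep(0L, 4)), cbind(rep(0L, 4)), rep("X", 4))
  h0 <- heterozygosity(ba0)
  expect_equal(h0$H_O, 0)
  expect_equal(h0$H_E, 0)
})

test_that("single-SNP observed heterozygosity averages per population", {
  H1 <- rbind(c(0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L))
  H2 <- rbind(c(1L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L))
  haps <- make_haps(H1, H2, c("X", "Y"))
  hs <- snp_observed_heterozygosity(haps)
  expect_equal(unname(hs["X"]), 0.25)   # het at 1 of 4 SNPs
  expect_equal(unname(hs["Y"]), 0)      # monomorphic
})

test_that("allelic richness matches hypergeometric rarefaction", {
  # counts {A:3, B:1}, g = 2 -> 1.5 by direct enumeration
  ba <- make_ba(cbind(c(0L, 0L)), cbind(c(0L, 1L)), rep("X", 2))
  ac <- tally_alleles(ba)
  expect_equal(unname(allelic_richness(ac, g = 2)), 1.5, tolerance = 1e-12,
               ignore_attr = TRUE)

  # richness at full depth equals the observed allele count, and is
  # non-decreasing in g
  ba2 <- random_ba(c(8, 8), n_blocks = 12, seed = 4)
  ac2 <- tally_alleles(ba2)
  g_full <- min(2 * ac2$n_typed)
  ar_prev <- -Inf
  for (g in c(2, 4, 8, g_full)) {
    ar_g <- allelic_richness(ac2, g = g)
    expect_true(all(ar_g >= ar_prev - 1e-12))
    ar_prev <- ar_g
  }
  # at g equal to every population's full copy count the identity is exact
  ba_eq <- random_ba(c(6, 6), n_blocks = 10, seed = 5)
  ac_eq <- tally_alleles(ba_eq)
  ar_full <- allelic_richness(ac_eq, g = 12)
  hand <- sapply(rownames(ac_eq$n_typed), function(p)
    mean(sapply(ac_eq$counts, function(cm) sum(cm[p, ] > 0))))
  expect_equal(unname(ar_full), unname(hand), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(allelic_richness(ac2, g = 1), "at least 2")
})

test_that("Weir-Cockerham statistics agree with the ANOVA oracle", {
  ba <- random_ba(c(10, 14, 8), n_blocks = 25, seed = 8)
  ours <- wc_fstats(ba)
  theirs <- oracle_wc(ba, ba$population)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10,
               ignore_attr = TRUE)

  # complete differentiation: two populations fixed for different alleles
  ba_fix <- make_ba(cbind(c(rep(0L, 5), rep(1L, 5))),
                    cbind(c(rep(0L, 5), rep(1L, 5))),
                    rep(c("X", "Y"), each = 5))
  theta <- wc_fstats(ba_fix)["F_ST"]
  expect_gt(theta, 0.95)
  expect_error(wc_fstats(make_ba(cbind(0:1), cbind(0:1), c("X", "Y"))),
               ">= 2 animals")
})

test_that("theta is near zero for a panmictic pool", {
  set.seed(42)
  n <- 200; B <- 200
  A1 <- matrix(0L, n, B); A2 <- matrix(0L, n, B)
  for (b in seq_len(B)) {
    f <- rgamma(5, 1); f <- f / sum(f)
    A1[, b] <- sample.int(5, n, TRUE, f) - 1L
    A2[, b] <- sample.int(5, n, TRUE, f) - 1L
  }
  ba <- make_ba(A1, A2, rep(c("X", "Y"), each = n / 2))
  expect_lt(abs(wc_fstats(ba)["F_ST"]), 0.02)
})

test_that("pairwise G_ST and D_EST behave at the differentiation extremes", {
  # identical allele-frequency profiles: no differentiation (within
  # small-sample estimator noise)
  A <- matrix(rep(c(0L, 1L, 2L, 3L), 25), 50, 8)
  ba_same <- make_ba(rbind(A, A), rbind(A[, ], A[, ]),
                     rep(c("X", "Y"), each = 50))
  ac_same <- tally_alleles(ba_same)
  expect_lt(abs(gst_pairwise(ac_same)["X", "Y"]), 0.01)
  expect_lt(abs(dest_pairwise(ac_same)["X", "Y"]), 0.05)

  # disjoint fixed alleles: both reach 1 exactly
  ba_fix <- make_ba(matrix(rep(c(0L, 1L), each = 6), 12, 3),
                    matrix(rep(c(0L, 1L), each = 6), 12, 3),
                    rep(c("X", "Y"), each = 6))
  ac_fix <- tally_alleles(ba_fix)
  expect_equal(gst_pairwise(ac_fix)["X", "Y"], 1, tolerance = 1e-12)
  expect_equal(dest_pairwise(ac_fix)["X", "Y"], 1, tolerance = 1e-12)
})

test_that("G_ST and D_EST match the loop oracle and are rank-concordant", {
  ba <- random_ba(c(12, 10, 14, 9, 11), n_blocks = 60,
                  drift = c(0.03, 0.08, 0.15, 0.3, 0.45), seed = 13)
  ac <- tally_alleles(ba)
  gst <- gst_pairwise(ac)
  dest <- dest_pairwise(ac)
  pops <- ac$pops
  for (i in 2:length(pops)) for (j in 1:(i - 1)) {
    o <- oracle_pair_stats(ba, ba$population, pops[i], pops[j])
    expect_equal(gst[pops[i], pops[j]], o$gst, tolerance = 1e-10)
    expect_equal(dest[pops[i], pops[j]], o$dest, tolerance = 1e-10)
  }
  ut <- upper.tri(gst)
  expect_gt(cor(gst[ut], dest[ut], method = "spearman"), 0.9)
  expect_true(all(sign(gst[ut]) == sign(dest[ut])))
})

test_that("per-block allele counts are conserved across populations", {
  ba <- random_ba(c(7, 9, 6), n_blocks = 15, seed = 17)
  ac <- tally_alleles(ba)
  for (b in seq_along(ac$counts)) {
    pooled_from_pops <- colSums(ac$counts[[b]])
    typed <- !is.na(ba$A1[, b])
    pooled_direct <- sapply(seq_along(pooled_from_pops) - 1L, function(al)
      sum(c(ba$A1[typed, b], ba$A2[typed, b]) == al))
    expect_identical(as.integer(pooled_from_pops), as.integer(pooled_direct))
  }
})

test_that("the diversity table assembles per-breed and pooled rows", {
  ba <- random_ba(c(10, 10), n_blocks = 20, seed = 23)
  tab <- summarize_diversity(ba)
  B <- attr(tab, "n_blocks")
  expect_equal(tab$mA, tab$nA / B, tolerance = 1e-12)
  all_row <- tab[tab$population == "All", ]
  per_pop <- tab[tab$population != "All", ]
  expect_identical(all_row$npA, as.integer(sum(per_pop$npA)))
  expect_equal(all_row$H_E, mean(per_pop$H_E))
  expect_gte(all_row$nA, max(per_pop$nA))

  # single population: everything it carries is private and common at once
  ba1 <- random_ba(c(12), n_blocks = 10, seed = 29)
  t1 <- summarize_diversity(ba1)
  expect_identical(t1$npA[1], t1$nA[1])
  expect_identical(t1$nrA[1], 0L)
  expect_identical(attr(t1, "ncA"), as.integer(t1$nA[1]))
})
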