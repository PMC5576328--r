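test_that("Yue-Clayton dissimilarity matches its closed forms", {
  v <- c(0.5, 0.3, 0.2)
  expect_equal(yue_clayton_dissimilarity(v, v), 0)
  expect_equal(yue_clayton_dissimilarity(c(1, 0), c(0, 1)), 1)
  expect_equal(yue_clayton_dissimilarity(c(0.8, 0.2), c(0.2, 0.8)),
               1 - 0.32 / 1.04, tolerance = 1e-12)
  expect_error(yue_clayton_dissimilarity(c(1, 0), c(0.5, 0.4)), "sum to 1")
  expect_error(yue_clayton_dissimilarity(c(1, 0), c(1, 0, 0)), "length")
})

test_that("Yue-Clayton is symmetric, permutation-invariant and scale-free", {
  set.seed(7)
  for (rep in 1:20) {
    a <- rgamma(8, 1); a <- a / sum(a)
    b <- rgamma(8, 1); b <- b / sum(b)
    d <- yue_clayton_dissimilarity(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(yue_clayton_dissimilarity(b, a), d)
    perm <- sample(8)
    expect_equal(yue_clayton_dissimilarity(a[perm], b[perm]), d)
    # proportional raw counts are identical after normalization
    expect_equal(yue_clayton_dissimilarity(7 * a, 3 * a, normalize = TRUE), 0)
  }
})

test_that("Bland-Altman limits of agreement match hand arithmetic", {
  ba <- bland_altman_pair(c(40, 30, 20, 10), c(30, 40, 20, 10))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_upper, 1.96 * sqrt(200 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_range, 2 * 1.96 * sqrt(200 / 3) / 100, tolerance = 1e-12)

  same <- bland_altman_pair(c(60, 30, 10), c(60, 30, 10))
  expect_equal(same$loa_range, 0)
  # constant differences: sd = 0, range 0 whatever the mean offset
  off <- bland_altman_pair(c(40, 35, 25), c(30, 25, 15))
  expect_equal(off$loa_range, 0)
  expect_equal(off$mean_diff, 10)
  expect_error(bland_altman_pair(c(1, 2), c(2, 1)), "3 taxa")
})

test_that("swapping the pair members negates the LOA bounds, not the range", {
  set.seed(12)
  for (rep in 1:10) {
    a <- rgamma(10, 1); a <- 100 * a / sum(a)
    b <- rgamma(10, 1); b <- 100 * b / sum(b)
    ab <- bland_altman_pair(a, b); ba <- bland_altman_pair(b, a)
    expect_equal(ba$mean_diff, -ab$mean_diff)
    expect_equal(ba$loa_lower, -ab$loa_upper)
    expect_equal(ba$loa_upper, -ab$loa_lower)
    expect_equal(ba$loa_range, ab$loa_range)
  }
})

test_that("group-level dissimilarity pools profiles and can hide pair differences", {
  tax <- setNames(paste0("k_B;p_P;c_C;o_O;f_F", 1:3, ";g_G", 1:3),
                  c("OTU_1", "OTU_2", "OTU_3"))
  # two pairs with crossed perturbations: each pair strongly discordant,
  # but the method-wise mean profiles coincide
  m <- matrix(c(80L, 10L, 10L,   # ISS_01
                10L, 80L, 10L,   # SSS_01
                10L, 80L, 10L,   # ISS_02
                80L, 10L, 10L),  # SSS_02
              nrow = 3,
              dimnames = list(c("OTU_1", "OTU_2", "OTU_3"),
                              c("ISS_01", "SSS_01", "ISS_02", "SSS_02")))
  pairing <- make_pairing(2)
  pc <- pair_concordance(m, tax, pairing)
  expect_true(all(pc$one_minus_theta_all > 0.5))
  expect_equal(group_mean_dissimilarity(m, tax, pairing), 0, tolerance = 1e-12)

  # identical methods across the board -> 0; and the definition matches
  # applying the index to the mean profiles directly
  m2 <- m; m2[, c("SSS_01", "SSS_02")] <- m2[, c("ISS_01", "ISS_02")]
  expect_equal(group_mean_dissimilarity(m2, tax, pairing), 0)
  rel <- to_relative(m)
  expect_equal(group_mean_dissimilarity(m, tax, pairing, level = NULL,
                                        otu_set = "all"),
               yue_clayton_dissimilarity(rowMeans(rel[, c(1, 3)]),
                                         rowMeans(rel[, c(2, 4)]),
                                         normalize = TRUE))
})

test_that("pair classification applies strict cut-offs", {
  pairs <- data.frame(pair_id = 1:4, state = c("stable", "stable",
                                               "exacerbation", "exacerbation"),
                      one_minus_theta_all = c(0.19, 0.21, 0.2, 0.05),
                      one_minus_theta_dom = c(0.19, 0.30, 0.2, 0.05),
                      loa_range = c(0.10, 0.11, 0.02, 0.3))
  out <- classify_pairs(pairs, theta_cut = 0.2, loa_cut = 0.1)
  expect_identical(out$theta_discordant_all, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(out$theta_discordant_dom, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(out$loa_discordant, c(FALSE, TRUE, FALSE, TRUE))
  s <- attr(out, "summary")
  expect_identical(s$theta_discordant_all[s$state == "all"], 1L)

  ident <- data.frame(pair_id = 1:3, state = "stable",
                      one_minus_theta_all = 0, one_minus_theta_dom = 0,
                      loa_range = 0)
  out2 <- classify_pairs(ident)
  expect_false(any(out2$theta_discordant_all | out2$loa_discordant))
})

test_that("G tests match hand evaluation and Bonferroni capping", {
  # two equal-size groups, taxon totals 10 vs 20
  tab <- matrix(c(4L, 6L, 9L, 11L), nrow = 1,
                dimnames = list("t1", c("a1", "a2", "b1", "b2")))
  groups <- setNames(c("g1", "g1", "g2", "g2"), colnames(tab))
  res <- taxon_g_test(tab, groups)
  expect_equal(res$G, 2 * (10 * log(10 / 15) + 20 * log(20 / 15)),
               tolerance = 1e-12)
  expect_identical(res$df, 1L)
  expect_equal(res$p_bonferroni, min(1, res$p_raw * 1))
  expect_equal(res$mean_g1, 5); expect_equal(res$mean_g2, 10)

  # equal totals with equal group sizes -> G = 0, p = 1
  tab0 <- matrix(c(7L, 8L, 6L, 9L), nrow = 1,
                 dimnames = list("t1", colnames(tab)))
  res0 <- taxon_g_test(tab0, groups)
  expect_equal(res0$G, 0); expect_equal(res0$p_raw, 1)

  # Bonferroni multiplies by the number of taxa tested, capped at 1
  expect_equal(min(1, 0.0002 * 106), 0.0212)
  many <- matrix(rpois(106 * 4, 30), nrow = 106,
                 dimnames = list(paste0("t", 1:106), colnames(tab)))
  storage.mode(many) <- "integer"
  resm <- taxon_g_test(many, groups)
  expect_equal(resm$p_bonferroni, pmin(1, resm$p_raw * 106))
  expect_true(all(resm$G >= 0))

  expect_error(taxon_g_test(tab, setNames(rep("g1", 4), colnames(tab))),
               "two groups")
})

test_that("G is zero exactly when group totals match expectation", {
  groups <- setNames(c("g1", "g1", "g1", "g2"), paste0("s", 1:4))
  # expectations proportional to group sizes 3:1
  tab <- matrix(c(9L, 2L, 1L, 4L,   # total 16, groups 12 vs 4 = 3:1 -> G = 0
                  5L, 5L, 5L, 5L),  # groups 15 vs 5 = 3:1 -> G = 0
                nrow = 2, byrow = TRUE,
                dimnames = list(c("t1", "t2"), paste0("s", 1:4)))
  res <- taxon_g_test(tab, groups)
  expect_equal(res$G, c(0, 0))
  tab[1, 4] <- 10L
  expect_gt(taxon_g_test(tab, groups)$G[1], 0)
})

test_that("the Williams correction shrinks G without changing its zeros", {
  groups <- setNames(c("g1", "g1", "g2", "g2"), paste0("s", 1:4))
  tab <- matrix(c(4L, 6L, 9L, 11L), nrow = 1,
                dimnames = list("t1", paste0("s", 1:4)))
  plain <- taxon_g_test(tab, groups, correction = "none")
  will <- taxon_g_test(tab, groups, correction = "williams")
  expect_lt(will$G, plain$G)
  expect_gt(will$G, 0)
})
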