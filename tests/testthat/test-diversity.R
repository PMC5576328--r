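test_that("richness measures match their closed forms", {
  expect_identical(observed_otus(c(3, 0, 1)), 2L)
  expect_identical(observed_otus(c(0, 0)), 0L)
  expect_equal(chao1(c(4, 2, 1, 1, 2)), 6)        # S=5, F1=2, F2=2
  expect_equal(chao1(c(1, 1)), 3)                 # F2 = 0 fallback
  expect_equal(chao1(c(5, 3, 4)), 3)              # no singletons -> S_obs
  set.seed(3)
  for (rep in 1:20) {
    col <- rpois(30, 1.2)
    expect_gte(chao1(col), observed_otus(col))
  }
})

test_that("Faith PD traces paths to the root and agrees with picante", {
  tree <- ape::read.tree(text = "((A:1,B:2):0.5,C:3):0;")
  tree$root.edge <- 0
  expect_equal(faith_pd(setNames(c(2, 0, 0), c("A", "B", "C")), tree), 1.5)
  expect_equal(faith_pd(setNames(c(1, 1, 1), c("A", "B", "C")), tree), 6.5)
  expect_equal(faith_pd(setNames(c(0, 0, 0), c("A", "B", "C")), tree), 0)
  expect_error(faith_pd(c(X = 3), tree), "missing from tree")

  skip_if_not_installed("picante")
  set.seed(21)
  for (rep in 1:15) {
    ts <- random_tree_and_samples(n_leaf = 10)
    col <- ts$cols[, 1]
    if (sum(col > 0) < 2) col[1:2] <- 1L  # picante needs >= 2 taxa
    samp <- matrix(col, nrow = 1, dimnames = list("s1", names(col)))
    expect_equal(faith_pd(col, ts$tree),
                 picante::pd(samp, ts$tree, include.root = TRUE)$PD,
                 tolerance = 1e-10)
  }
})

test_that("Faith PD never decreases when an OTU is added", {
  set.seed(8)
  for (rep in 1:10) {
    ts <- random_tree_and_samples(n_leaf = 8)
    col <- ts$cols[, 1]
    absent <- which(col == 0)
    if (!length(absent)) next
    col2 <- col; col2[absent[1]] <- 1L
    expect_gte(faith_pd(col2, ts$tree), faith_pd(col, ts$tree))
  }
})

test_that("UniFrac matches its worked branch tallies", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2):0;")
  s1 <- setNames(c(1, 1, 0), c("A", "B", "C"))
  s2 <- setNames(c(1, 0, 1), c("A", "B", "C"))
  expect_equal(unweighted_unifrac(s1, s2, tree), 0.6)  # unique 3 / covered 5
  expect_equal(unweighted_unifrac(s1, s1, tree), 0)

  two <- ape::read.tree(text = "(A:1,B:1):0;")
  allA <- setNames(c(4, 0), c("A", "B")); allB <- setNames(c(0, 7), c("A", "B"))
  expect_equal(weighted_unifrac(allA, allB, two), 2)
  # moving mass eps from A to B moves the raw distance by 2*eps
  for (eps in c(0.1, 0.25, 0.4)) {
    mix <- setNames(c(100 * (1 - eps), 100 * eps), c("A", "B"))
    expect_equal(weighted_unifrac(allA, mix, two), 2 * eps, tolerance = 1e-12)
  }
  # proportional columns: same composition, different depth -> 0
  expect_equal(weighted_unifrac(setNames(c(30, 10), c("A", "B")),
                                setNames(c(3, 1), c("A", "B")), two), 0)
  # star tree with disjoint leaf sets -> unweighted distance 1
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1):0;")
  expect_equal(unweighted_unifrac(setNames(c(1, 1, 0, 0), LETTERS[1:4]),
                                  setNames(c(0, 0, 2, 3), LETTERS[1:4]), star), 1)
  expect_error(unweighted_unifrac(s1, setNames(c(0, 0, 0), c("A", "B", "C")),
                                  tree), "empty")
})

test_that("both UniFrac forms agree with an independent per-branch oracle", {
  skip_if_not_installed("phangorn")
  set.seed(14)
  for (rep in 1:30) {
    ts <- random_tree_and_samples(n_leaf = 8)
    a <- ts$cols[, 1]; b <- ts$cols[, 2]
    expect_equal(unweighted_unifrac(a, b, ts$tree),
                 oracle_unifrac(a, b, ts$tree, "unweighted"), tolerance = 1e-10)
    expect_equal(weighted_unifrac(a, b, ts$tree),
                 oracle_unifrac(a, b, ts$tree, "weighted"), tolerance = 1e-10)
    expect_equal(weighted_unifrac(a, b, ts$tree, normalized = TRUE),
                 oracle_unifrac(a, b, ts$tree, "weighted", normalized = TRUE),
                 tolerance = 1e-10)
    # metric sanity on the same draw
    expect_equal(unweighted_unifrac(b, a, ts$tree),
                 unweighted_unifrac(a, b, ts$tree))
    d <- unweighted_unifrac(a, b, ts$tree)
    expect_gte(d, 0); expect_lte(d, 1)
    dn <- weighted_unifrac(a, b, ts$tree, normalized = TRUE)
    expect_gte(dn, 0); expect_lte(dn, 1)
  }
})

test_that("UniFrac agrees with phyloseq on random trees", {
  skip_if_not_installed("phyloseq")
  set.seed(15)
  for (rep in 1:5) {
    ts <- random_tree_and_samples(n_leaf = 12)
    otu <- phyloseq::otu_table(ts$cols, taxa_are_rows = TRUE)
    ps <- phyloseq::phyloseq(otu, phyloseq::phy_tree(ts$tree))
    expect_equal(unweighted_unifrac(ts$cols[, 1], ts$cols[, 2], ts$tree),
                 as.numeric(phyloseq::UniFrac(ps, weighted = FALSE)),
                 tolerance = 1e-8)
    expect_equal(weighted_unifrac(ts$cols[, 1], ts$cols[, 2], ts$tree,
                                  normalized = TRUE),
                 as.numeric(phyloseq::UniFrac(ps, weighted = TRUE,
                                              normalized = TRUE)),
                 tolerance = 1e-8)
  }
})

test_that("the UniFrac distance matrix reproduces pairwise calls", {
  set.seed(16)
  ts <- random_tree_and_samples(n_leaf = 10)
  m <- cbind(ts$cols, c = as.integer(ts$cols[, 1] + 1L))
  dm <- unifrac_matrix(m, ts$tree, metric = "weighted")
  expect_equal(dm["a", "c"], weighted_unifrac(m[, "a"], m[, "c"], ts$tree))
  expect_true(isSymmetric(dm))
  expect_equal(diag(dm), setNames(rep(0, 3), colnames(m)))
  dmu <- unifrac_matrix(m, ts$tree, metric = "unweighted")
  expect_equal(dmu["b", "c"], unweighted_unifrac(m[, "b"], m[, "c"], ts$tree))
})

test_that("UniFrac pair significance behaves at its fixed points", {
  set.seed(17)
  ts <- random_tree_and_samples(n_leaf = 8, max_count = 20)
  a <- ts$cols[, 1]
  res <- unifrac_pair_significance(a, a, ts$tree, metric = "weighted",
                                   n_perm = 100, seed = 9)
  expect_equal(res$observed, 0)
  expect_equal(res$p, 1)  # every permuted distance >= 0

  b <- ts$cols[, 2]
  r_ab <- unifrac_pair_significance(a, b, ts$tree, n_perm = 150, seed = 4)
  r_ba <- unifrac_pair_significance(b, a, ts$tree, n_perm = 150, seed = 4)
  expect_equal(r_ab$p, r_ba$p)  # labeling order cannot matter
  expect_error(unifrac_pair_significance(a, b, ts$tree, n_perm = 10), ">= 100")
})

test_that("72 samples generate 2556 unordered comparisons", {
  expect_identical(nrow(t(utils::combn(72, 2))), 2556L)
  # and the driver Bonferroni-corrects by comparisons actually run
  set.seed(18)
  ts <- random_tree_and_samples(n_leaf = 6, max_count = 15)
  m <- cbind(ts$cols, c = as.integer(ts$cols[, 2] + 2L),
             d = as.integer(rev(ts$cols[, 1]) + 1L))
  rownames(m) <- rownames(ts$cols)
  out <- unifrac_pairwise_tests(m, ts$tree, scope = "all", n_perm = 100, seed = 2)
  expect_identical(nrow(out), 6L)  # 4 choose 2
  expect_equal(out$p_bonferroni, pmin(1, out$p_raw * 6))
})

test_that("the permutation t-test matches its fixed points", {
  same <- c(3.1, 2.9, 3.0, 3.2)
  res <- alpha_group_test(same, same, n_perm = 199, seed = 1)
  expect_gt(res$p, 0.9)

  sep <- alpha_group_test(c(1, 2, 3), c(101, 102, 103), n_perm = 999, seed = 2)
  # complete separation: the two extreme splits of the 20 possible label
  # assignments reach |t_obs|, so p concentrates near 2/20 = 0.1
  expect_lt(sep$p, 0.2)
  expect_gt(abs(sep$t_statistic), 50)
  expect_error(alpha_group_test(1, c(2, 3)), "two values")
})
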