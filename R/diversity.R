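#' Observed OTU richness of one sample
#' @param column integer count vector for one (rarefied) sample.
#' @return number of OTUs with count > 0.
#' @export
observed_otus <- function(column) sum(column > 0)

#' Chao1 richness estimate of one sample
#'
#' Classic Chao1: S_obs + F1^2 / (2 F2) when doubletons are present, and the
#' bias-corrected fallback S_obs + F1 (F1 - 1) / 2 when F2 = 0, where F1 and
#' F2 are the numbers of singleton and doubleton OTUs.
#'
#' @param column integer count vector for one (rarefied) sample.
#' @return richness estimate, always >= observed richness.
#' @export
chao1 <- function(column) {
  s_obs <- sum(column > 0)
  f1 <- sum(column == 1)
  f2 <- sum(column == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Faith's phylogenetic diversity of one sample
#'
#' Sum of branch lengths on the union of root-to-leaf paths over the OTUs
#' observed in the sample, including the root's own edge when the tree
#' carries one.
#'
#' @param column named integer count vector (names = OTU ids) or a vector
#'   aligned with `tree$tip.label`.
#' @param tree rooted [ape::phylo] tree whose leaves include every observed OTU.
#' @return total branch length spanned; 0 for an empty sample.
#' @export
faith_pd <- function(column, tree) {
  idx <- tree_index(tree)
  p <- align_to_tips(column, idx)
  if (sum(p) == 0) return(0)
  present <- drop(idx$leaf_desc %*% (p > 0)) > 0
  sum(idx$edge_length[present]) + idx$root_edge
}

# Align a whole count table onto the tree's leaf ordering (zero rows for
# leaves absent from the table; error if an OTU with counts is not a leaf).
align_table_to_tips <- function(table, idx) {
  if (is.null(rownames(table)))
    stop("count table must carry OTU row names to be matched to the tree")
  extra <- setdiff(rownames(table)[rowSums(table) > 0], idx$tip_label)
  if (length(extra))
    stop("observed OTU(s) missing from tree: ", paste(extra, collapse = ", "))
  out <- matrix(0, length(idx$tip_label), ncol(table),
                dimnames = list(idx$tip_label, colnames(table)))
  shared <- intersect(rownames(table), idx$tip_label)
  out[shared, ] <- table[shared, ]
  out
}

# Map a (possibly named) sample vector onto the tree's leaf ordering.
align_to_tips <- function(column, idx) {
  if (!is.null(names(column))) {
    extra <- setdiff(names(column)[column > 0], idx$tip_label)
    if (length(extra))
      stop("observed OTU(s) missing from tree: ", paste(extra, collapse = ", "))
    out <- stats::setNames(numeric(length(idx$tip_label)), idx$tip_label)
    shared <- intersect(names(column), idx$tip_label)
    out[shared] <- column[shared]
    out
  } else {
    if (length(column) != length(idx$tip_label))
      stop("unnamed sample vector must match the tree's leaf count")
    column
  }
}

# Branch-wise sample proportions: for each edge, the fraction of the
# sample's sequences descending from that edge's child.
branch_proportions <- function(columns, idx) {
  totals <- colSums(columns)
  if (any(totals == 0)) stop("empty sample in UniFrac computation")
  idx$leaf_desc %*% sweep(columns, 2L, totals, "/")
}

#' Unweighted UniFrac distance between two samples
#'
#' Presence/absence form: branch length found under exactly one of the two
#' samples' observed leaf sets, divided by branch length found under either.
#' Branches with no observed descendant in either sample are excluded.
#'
#' @param col_a,col_b named count vectors (or vectors aligned with the
#'   tree's leaves).
#' @param tree rooted [ape::phylo] tree.
#' @return distance in `[0, 1]`.
#' @export
unweighted_unifrac <- function(col_a, col_b, tree) {
  idx <- tree_index(tree)
  cols <- cbind(align_to_tips(col_a, idx), align_to_tips(col_b, idx))
  if (any(colSums(cols) == 0)) stop("UniFrac undefined for an empty sample")
  pres <- idx$leaf_desc %*% (cols > 0) > 0
  covered <- pres[, 1L] | pres[, 2L]
  unique_len <- sum(idx$edge_length[xor(pres[, 1L], pres[, 2L])])
  unique_len / sum(idx$edge_length[covered])
}

#' Weighted UniFrac distance between two samples
#'
#' Quantitative form: sum over branches of branch length times the absolute
#' difference in the fraction of each sample's sequences descending through
#' the branch. The raw form is returned by default; `normalized = TRUE`
#' divides by the abundance-weighted average root-to-leaf depth, scaling the
#' distance into `[0, 1]`.
#'
#' @inheritParams unweighted_unifrac
#' @param normalized return the normalized form.
#' @return distance >= 0 (raw) or in `[0, 1]` (normalized).
#' @export
weighted_unifrac <- function(col_a, col_b, tree, normalized = FALSE) {
  idx <- tree_index(tree)
  cols <- cbind(align_to_tips(col_a, idx), align_to_tips(col_b, idx))
  p <- branch_proportions(cols, idx)
  raw <- sum(idx$edge_length * abs(p[, 1L] - p[, 2L]))
  if (!normalized) return(raw)
  raw / sum(idx$edge_length * (p[, 1L] + p[, 2L]))
}

#' All-pairs UniFrac distance matrix
#'
#' @param table count table whose rows are leaves of `tree`.
#' @param tree rooted [ape::phylo] tree.
#' @param metric `"unweighted"` or `"weighted"`.
#' @param normalized normalization flag for the weighted form.
#' @return symmetric sample x sample distance matrix.
#' @export
unifrac_matrix <- function(table, tree,
                           metric = c("weighted", "unweighted"),
                           normalized = FALSE) {
  metric <- match.arg(metric)
  idx <- tree_index(tree)
  cols <- align_table_to_tips(table, idx)
  n <- ncol(cols)
  d <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  if (metric == "weighted") {
    p <- branch_proportions(cols, idx)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      raw <- sum(idx$edge_length * abs(p[, i] - p[, j]))
      d[i, j] <- d[j, i] <- if (normalized)
        raw / sum(idx$edge_length * (p[, i] + p[, j])) else raw
    }
  } else {
    pres <- idx$leaf_desc %*% (cols > 0) > 0
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      covered <- pres[, i] | pres[, j]
      uniq <- xor(pres[, i], pres[, j])
      d[i, j] <- d[j, i] <- sum(idx$edge_length[uniq]) / sum(idx$edge_length[covered])
    }
  }
  d
}

#' Monte-Carlo significance of the UniFrac distance between two samples
#'
#' Null model: each sequence is randomly reassigned to one of the two
#' samples, keeping both sample depths fixed (a multivariate hypergeometric
#' split of the pooled counts). The p-value uses the add-one estimator
#' p = (1 + #\{permuted distance >= observed\}) / (1 + n_perm).
#'
#' @inheritParams unweighted_unifrac
#' @param metric `"weighted"` or `"unweighted"`.
#' @param normalized normalization flag for the weighted form.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with `observed`, `p`, `n_perm`.
#' @export
unifrac_pair_significance <- function(col_a, col_b, tree,
                                      metric = c("weighted", "unweighted"),
                                      normalized = FALSE, n_perm = 1000,
                                      seed = NULL) {
  metric <- match.arg(metric)
  if (n_perm < 100) stop("n_perm must be >= 100")
  idx <- tree_index(tree)
  cols <- cbind(align_to_tips(col_a, idx), align_to_tips(col_b, idx))
  dist_fun <- function(cc) {
    if (metric == "weighted") {
      p <- branch_proportions(cc, idx)
      raw <- sum(idx$edge_length * abs(p[, 1L] - p[, 2L]))
      if (normalized) raw / sum(idx$edge_length * (p[, 1L] + p[, 2L])) else raw
    } else {
      pres <- idx$leaf_desc %*% (cc > 0) > 0
      covered <- pres[, 1L] | pres[, 2L]
      sum(idx$edge_length[xor(pres[, 1L], pres[, 2L])]) /
        sum(idx$edge_length[covered])
    }
  }
  obs <- dist_fun(cols)
  pooled <- as.integer(rowSums(cols))
  # draw the smaller depth; the complement carries the larger. The metric is
  # symmetric, so the p-value is exactly invariant to the samples' order.
  depth_small <- min(colSums(cols))
  depth_large <- sum(pooled) - depth_small
  el <- idx$edge_length
  # permutations are evaluated in batches through one branch-propagation
  # matrix product per batch rather than one per permutation
  run <- function() {
    hits <- 0L
    left <- n_perm
    while (left > 0L) {
      nb <- min(left, 500L)
      A <- vapply(seq_len(nb), function(b) rmvhyper_counts(pooled, depth_small),
                  integer(length(pooled)))
      if (metric == "weighted") {
        pa <- (idx$leaf_desc %*% A) / depth_small
        pb <- (drop(idx$leaf_desc %*% pooled) - idx$leaf_desc %*% A) / depth_large
        d <- colSums(el * abs(pa - pb))
        if (normalized) d <- d / colSums(el * (pa + pb))
      } else {
        presA <- (idx$leaf_desc %*% (A > 0)) > 0
        presB <- (idx$leaf_desc %*% ((pooled - A) > 0)) > 0
        d <- colSums(el * xor(presA, presB)) / colSums(el * (presA | presB))
      }
      hits <- hits + sum(d >= obs - 1e-12)
      left <- left - nb
    }
    hits
  }
  hits <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(observed = obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}

#' Pairwise UniFrac significance tests with Bonferroni correction
#'
#' Runs [unifrac_pair_significance()] over a set of sample pairs — either
#' every unordered pair of columns (`scope = "all"`, the 2556 comparisons of
#' a 72-sample study) or only the matched within-pair comparisons
#' (`scope = "paired"`) — and Bonferroni-corrects by the number of
#' comparisons actually run.
#'
#' @param table count table.
#' @param tree rooted [ape::phylo] tree.
#' @param pairing pairing table (required for `scope = "paired"`).
#' @param scope `"paired"` or `"all"`.
#' @inheritParams unifrac_pair_significance
#' @return data frame with columns `sample_a`, `sample_b`, `distance`,
#'   `p_raw`, `p_bonferroni` (and `pair_id` for paired scope).
#' @export
unifrac_pairwise_tests <- function(table, tree, pairing = NULL,
                                   scope = c("paired", "all"),
                                   metric = c("weighted", "unweighted"),
                                   normalized = FALSE, n_perm = 1000,
                                   seed = NULL) {
  scope <- match.arg(scope)
  metric <- match.arg(metric)
  if (scope == "paired") {
    if (is.null(pairing)) stop("paired scope needs a pairing table")
    ab <- cbind(pairing$induced_id, pairing$spontaneous_id)
  } else {
    ids <- colnames(table)
    ab <- t(utils::combn(ids, 2L))
  }
  m <- nrow(ab)
  res <- vector("list", m)
  for (k in seq_len(m)) {
    s <- if (is.null(seed)) NULL else child_seed(seed, paste0("unifrac_pair_", k))
    r <- unifrac_pair_significance(table[, ab[k, 1L]], table[, ab[k, 2L]], tree,
                                   metric = metric, normalized = normalized,
                                   n_perm = n_perm, seed = s)
    res[[k]] <- data.frame(sample_a = ab[k, 1L], sample_b = ab[k, 2L],
                           distance = r$observed, p_raw = r$p,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p_raw * m)
  if (scope == "paired") out <- cbind(pair_id = pairing$pair_id, out)
  out
}

#' Per-sample alpha diversity
#'
#' @param table rarefied count table.
#' @param tree rooted [ape::phylo] tree (for Faith's PD).
#' @return data frame with `sample_id`, `observed_otus`, `chao1`, `faith_pd`.
#' @export
alpha_diversity <- function(table, tree) {
  idx <- tree_index(tree)
  aligned <- align_table_to_tips(table, idx)
  pd <- vapply(seq_len(ncol(aligned)), function(j) {
    p <- aligned[, j]
    if (sum(p) == 0) return(0)
    present <- drop(idx$leaf_desc %*% (p > 0)) > 0
    sum(idx$edge_length[present]) + idx$root_edge
  }, numeric(1))
  data.frame(sample_id = colnames(table),
             observed_otus = apply(table, 2L, observed_otus),
             chao1 = apply(table, 2L, chao1),
             faith_pd = pd,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Non-parametric two-sample t-test by Monte-Carlo permutation
#'
#' Computes the two-sample t statistic on the observed grouping and compares
#' its absolute value against random relabelings of the pooled values;
#' p = (1 + #\{|t_perm| >= |t_obs|\}) / (1 + n_perm).
#'
#' @param values_a,values_b numeric vectors (>= 2 values each).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `t_statistic`, `p`, `n_perm`.
#' @export
alpha_group_test <- function(values_a, values_b, n_perm = 999, seed = NULL) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("need at least two values per group")
  tstat <- function(x, y) {
    se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
    if (se == 0) return(0)
    (mean(x) - mean(y)) / se
  }
  t_obs <- tstat(values_a, values_b)
  pooled <- c(values_a, values_b)
  na <- length(values_a)
  run <- function() {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(pooled), na)
      if (abs(tstat(pooled[idx], pooled[-idx])) >= abs(t_obs) - 1e-12)
        hits <- hits + 1L
    }
    hits
  }
  hits <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(t_statistic = t_obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}
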