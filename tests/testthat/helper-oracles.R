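# Fixture builders and independent oracles used across the suite.

# Small random count table with named axes.
random_count_table <- function(n_otu = 6, n_sample = 4, lambda = 20) {
  m <- matrix(rpois(n_otu * n_sample, lambda), n_otu, n_sample,
              dimnames = list(paste0("OTU_", seq_len(n_otu)),
                              paste0("S", seq_len(n_sample))))
  storage.mode(m) <- "integer"
  m
}

# Per-branch UniFrac tally through an independent route: descendant tip sets
# come from phangorn::Descendants, not from the package's postorder index.
oracle_unifrac <- function(col_a, col_b, tree, metric, normalized = FALSE) {
  tips <- tree$tip.label
  a <- col_a[tips]; b <- col_b[tips]
  pa <- a / sum(a); pb <- b / sum(b)
  uniq <- 0; covered <- 0; raw <- 0; depth_mass <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    below <- unlist(phangorn::Descendants(tree, child, type = "tips"))
    pA <- sum(pa[below]); pB <- sum(pb[below])
    hasA <- any(a[below] > 0); hasB <- any(b[below] > 0)
    if (hasA || hasB) covered <- covered + len
    if (xor(hasA, hasB)) uniq <- uniq + len
    raw <- raw + len * abs(pA - pB)
    depth_mass <- depth_mass + len * (pA + pB)
  }
  if (metric == "unweighted") return(uniq / covered)
  if (normalized) raw / depth_mass else raw
}

# ANOSIM statistic straight from its definition, with explicit loops.
oracle_anosim_r <- function(dm, groups) {
  n <- nrow(dm)
  d <- c(); between <- c()
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    d <- c(d, dm[i, j])
    between <- c(between, groups[i] != groups[j])
  }
  r <- rank(d)
  m <- length(d)
  (mean(r[between]) - mean(r[!between])) / (m / 2)
}

# Random rooted tree with unit-scale branch lengths and sample columns on it.
random_tree_and_samples <- function(n_leaf = 8, max_count = 10) {
  tree <- ape::rtree(n_leaf, rooted = TRUE, br = function(k) runif(k, 0.1, 2))
  tree$root.edge <- 0
  cols <- matrix(sample(0:max_count, 2 * n_leaf, replace = TRUE), n_leaf, 2,
                 dimnames = list(tree$tip.label, c("a", "b")))
  # ensure both samples are non-empty
  if (sum(cols[, 1]) == 0) cols[1, 1] <- 1L
  if (sum(cols[, 2]) == 0) cols[2, 2] <- 1L
  storage.mode(cols) <- "integer"
  list(tree = tree, cols = cols)
}

# A tiny pairing table over a count table's columns.
make_pairing <- function(n_pairs, states = NULL) {
  data.frame(pair_id = seq_len(n_pairs),
             induced_id = sprintf("ISS_%02d", seq_len(n_pairs)),
             spontaneous_id = sprintf("SSS_%02d", seq_len(n_pairs)),
             state = states %||% rep("stable", n_pairs),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
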