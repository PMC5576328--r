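#' Yue-Clayton dissimilarity between two composition vectors
#'
#' Computes 1 - theta where theta = sum(a*b) / (sum(a^2) + sum(b^2) -
#' sum(a*b)). Theta weighs both shared and unshared components of the two
#' communities; 1 - theta is 0 for identical compositions and 1 for
#' completely disjoint ones.
#'
#' @param a,b relative-abundance vectors of equal length, each summing to 1
#'   (tolerance 1e-6). Set `normalize = TRUE` to rescale raw counts or
#'   percentages first.
#' @param normalize divide each vector by its sum before comparing.
#' @return dissimilarity in `[0, 1]`.
#' @export
yue_clayton_dissimilarity <- function(a, b, normalize = FALSE) {
  if (length(a) != length(b)) stop("profiles differ in length")
  if (normalize) {
    if (sum(a) <= 0 || sum(b) <= 0) stop("cannot normalize an all-zero profile")
    a <- a / sum(a); b <- b / sum(b)
  }
  if (abs(sum(a) - 1) > 1e-6 || abs(sum(b) - 1) > 1e-6)
    stop("profiles must each sum to 1 (use normalize = TRUE for raw input)")
  cross <- sum(a * b)
  denom <- sum(a^2) + sum(b^2) - cross
  theta <- cross / denom
  min(max(1 - theta, 0), 1)
}

#' Group-level Yue-Clayton dissimilarity between sampling methods
#'
#' Averages the relative-abundance profiles of all induced samples and of all
#' spontaneous samples in a disease-state subset, renormalises the two mean
#' profiles, and returns their Yue-Clayton dissimilarity. Pooling this way
#' can hide differences visible pair by pair, which is exactly the contrast
#' the per-pair statistics are there to expose.
#'
#' @param table count table (OTU level).
#' @param tax taxonomy map (lineage strings by OTU id).
#' @param pairing validated pairing table.
#' @param subset `"all"`, `"exacerbation"` or `"stable"`.
#' @param otu_set `"all"` or `"dominant"` (OTUs holding >= `dominant_fraction`
#'   of all sequences, filtered before collapsing to taxa).
#' @param level taxonomic level for collapsing (6 = genus); `NULL` compares
#'   OTU-level profiles.
#' @param dominant_fraction threshold for the dominant set.
#' @return dissimilarity in `[0, 1]`.
#' @export
group_mean_dissimilarity <- function(table, tax, pairing,
                                     subset = c("all", "exacerbation", "stable"),
                                     otu_set = c("all", "dominant"),
                                     level = 6L, dominant_fraction = 0.01) {
  otu_set <- match.arg(otu_set)
  sub <- subset_pairing(pairing, match.arg(subset))
  tab <- if (otu_set == "dominant") filter_dominant(table, dominant_fraction) else table
  if (!is.null(level)) tab <- collapse_taxonomy(tab, tax, level)
  rel <- to_relative(tab)
  mean_ind <- rowMeans(rel[, sub$induced_id, drop = FALSE])
  mean_spo <- rowMeans(rel[, sub$spontaneous_id, drop = FALSE])
  yue_clayton_dissimilarity(mean_ind, mean_spo, normalize = TRUE)
}

#' Bland-Altman limits of agreement for one sample pair
#'
#' Takes the two members' taxon abundances in percent, forms the per-taxon
#' differences d = a - b, and returns the mean difference, the 95% limits of
#' agreement mean(d) +/- 1.96 sd(d) (sample sd, n - 1), and the range
#' statistic (upper - lower) / 100, a 0-1 number where 0 is perfect
#' agreement.
#'
#' @param a,b percent-abundance vectors (each summing to 100) of equal
#'   length >= 3.
#' @return list with `mean_diff`, `loa_lower`, `loa_upper`, `loa_range`.
#' @export
bland_altman_pair <- function(a, b) {
  if (length(a) != length(b)) stop("profiles differ in length")
  if (length(a) < 3L) stop("need at least 3 taxa for limits of agreement")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m,
       loa_lower = m - 1.96 * s,
       loa_upper = m + 1.96 * s,
       loa_range = (2 * 1.96 * s) / 100)
}

#' Per-pair concordance statistics
#'
#' For every sample pair computes the Yue-Clayton dissimilarity on the full
#' taxon profile and on the dominant-OTU taxon profile, and the Bland-Altman
#' limits of agreement on the full taxon profile in percent.
#'
#' @inheritParams group_mean_dissimilarity
#' @param otu_level if `TRUE`, the "all" dissimilarity is computed on
#'   OTU-level rather than taxon-level profiles.
#' @return data frame with one row per pair: `pair_id`, `state`,
#'   `one_minus_theta_all`, `one_minus_theta_dom`, `mean_diff`, `loa_lower`,
#'   `loa_upper`, `loa_range`.
#' @export
pair_concordance <- function(table, tax, pairing, level = 6L,
                             dominant_fraction = 0.01, otu_level = FALSE) {
  pairing <- validate_pairing(pairing, table)
  if (nrow(pairing) == 0L) stop("empty pairing")
  taxa_all <- collapse_taxonomy(table, tax, level)
  taxa_dom <- collapse_taxonomy(filter_dominant(table, dominant_fraction), tax, level)
  rel_all <- to_relative(if (otu_level) table else taxa_all)
  rel_dom <- to_relative(taxa_dom)
  pct_all <- to_relative(taxa_all, percent = TRUE)
  # a sample can lack dominant-set reads entirely: disjoint support against a
  # non-empty partner is complete dissimilarity; two empty profiles carry no
  # information
  yc_safe <- function(a, b) {
    ea <- sum(a) == 0; eb <- sum(b) == 0
    if (ea && eb) return(NA_real_)
    if (ea || eb) return(1)
    yue_clayton_dissimilarity(a, b, normalize = TRUE)
  }
  rows <- lapply(seq_len(nrow(pairing)), function(i) {
    ind <- pairing$induced_id[i]; spo <- pairing$spontaneous_id[i]
    ba <- bland_altman_pair(pct_all[, ind], pct_all[, spo])
    data.frame(
      pair_id = pairing$pair_id[i],
      state = pairing$state[i],
      one_minus_theta_all = yc_safe(rel_all[, ind], rel_all[, spo]),
      one_minus_theta_dom = yc_safe(rel_dom[, ind], rel_dom[, spo]),
      mean_diff = ba$mean_diff,
      loa_lower = ba$loa_lower,
      loa_upper = ba$loa_upper,
      loa_range = ba$loa_range,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify sample pairs as concordant or discordant
#'
#' Applies the concordance cut-offs to per-pair statistics (strict `>`
#' comparison: a pair exactly at a cut-off counts as concordant). The default
#' cut-offs are 0.2 for within-pair 1 - theta and 0.1 for the Bland-Altman
#' LOA range.
#'
#' @param pairs data frame from [pair_concordance()].
#' @param theta_cut acceptable within-pair 1 - theta.
#' @param loa_cut acceptable LOA range.
#' @return `pairs` with logical columns `theta_discordant_all`,
#'   `theta_discordant_dom`, `loa_discordant`, plus attribute `"summary"`
#'   holding per-state discordance counts.
#' @export
classify_pairs <- function(pairs, theta_cut = 0.2, loa_cut = 0.1) {
  pairs$theta_discordant_all <- pairs$one_minus_theta_all > theta_cut
  pairs$theta_discordant_dom <- pairs$one_minus_theta_dom > theta_cut
  pairs$loa_discordant <- pairs$loa_range > loa_cut
  states <- sort(unique(pairs$state))
  count_by <- function(flag) c(sum(flag, na.rm = TRUE),
                               tapply(flag, pairs$state, sum, na.rm = TRUE)[states])
  attr(pairs, "summary") <- data.frame(
    state = c("all", states),
    n_pairs = c(nrow(pairs), as.vector(table(pairs$state)[states])),
    theta_discordant_all = count_by(pairs$theta_discordant_all),
    theta_discordant_dom = count_by(pairs$theta_discordant_dom),
    loa_discordant = count_by(pairs$loa_discordant),
    row.names = NULL)
  pairs
}

#' Per-taxon log-likelihood ratio (G) tests between sample groups
#'
#' For each taxon, compares the total sequence count per group against
#' expectations proportional to group sample sizes under homogeneity:
#' G = 2 * sum_g O_g log(O_g / E_g), zero-count groups contributing 0,
#' with a chi-square reference on `n_groups - 1` degrees of freedom and
#' Bonferroni correction over the taxa tested. Run on a table rarefied to a
#' common depth so that group totals are comparable.
#'
#' @param taxa_table taxon x sample count matrix (rarefied).
#' @param groups factor or character vector of group labels, either named by
#'   sample id or aligned with the table's columns.
#' @param correction `"none"` (default) or `"williams"` (divides G by the
#'   Williams q factor for the goodness-of-fit layout).
#' @return data frame with one row per taxon: group means, `G`, `df`,
#'   `p_raw`, `p_bonferroni`, sorted by `p_raw`.
#' @export
taxon_g_test <- function(taxa_table, groups, correction = c("none", "williams")) {
  correction <- match.arg(correction)
  if (!is.null(names(groups))) groups <- groups[colnames(taxa_table)]
  if (length(groups) != ncol(taxa_table) || anyNA(groups))
    stop("every sample must be assigned to a group")
  groups <- factor(as.character(groups))
  n_g <- table(groups)
  if (length(n_g) < 2L) stop("need at least two groups")
  if (any(n_g == 0L)) stop("empty group")
  O <- t(rowsum(t(taxa_table), group = groups))        # taxa x groups
  totals <- rowSums(O)
  E <- outer(totals, as.numeric(n_g) / sum(n_g))
  terms <- O * log(ifelse(O > 0, O / E, 1))
  G <- 2 * rowSums(terms)
  G <- pmax(G, 0)
  if (correction == "williams") {
    k <- length(n_g)
    q <- 1 + (k^2 - 1) / (6 * pmax(totals, 1) * (k - 1))
    G <- G / q
  }
  df <- length(n_g) - 1L
  p_raw <- stats::pchisq(G, df = df, lower.tail = FALSE)
  means <- sweep(O, 2L, as.numeric(n_g), "/")
  colnames(means) <- paste0("mean_", levels(groups))
  out <- data.frame(taxon = rownames(taxa_table), means, G = G, df = df,
                    p_raw = p_raw,
                    p_bonferroni = pmin(1, p_raw * nrow(taxa_table)),
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out[order(out$p_raw), ]
}
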