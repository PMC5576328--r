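#' Configuration for the paired-community simulator
#'
#' Defaults emulate the design of a 36-pair induced/spontaneous sputum
#' study: ~1000 OTUs collapsing to 106 genus-level taxa, sequencing depths
#' drawn uniformly from [0.8, 1.2] x 25000 so every sample exceeds the
#' rarefaction depths used downstream (18250 / 19743), 11 stable pairs
#' followed by 25 exacerbation pairs, and a per-pair divergence parameter
#' sweeping from 0 (identical compositions) to 2 (strongly discordant).
#'
#' @param n_pairs number of sample pairs.
#' @param n_otus number of OTUs.
#' @param n_genera number of genus-level taxa the OTUs collapse to.
#' @param depth_mean mean sequencing depth (sequences/sample).
#' @param depth_dispersion half-width of the uniform depth multiplier
#'   (depths ~ U[(1-d), (1+d)] x depth_mean).
#' @param base_concentration Dirichlet concentration tying each pair's base
#'   composition to the global mean profile (larger = more similar subjects).
#' @param divergence per-pair log-abundance perturbation sd sigma; scalar or
#'   length-`n_pairs` vector; 0 gives identical paired compositions.
#' @param state_split fraction of pairs labelled `exacerbation` (the stable
#'   pairs come first, as in the study's pair numbering).
#' @param effect_taxa named numeric vector of fold-changes applied to the
#'   spontaneous member, names matching genus labels (`"g_5"` style index
#'   labels, see [simulate_paired_tables()]).
#' @param perturbation `"logistic_normal"` (default) or `"dirichlet"`
#'   (spontaneous composition resampled as Dirichlet(c * pi) with
#'   c = 1/divergence^2).
#' @param seed integer master seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_pairs = 36L, n_otus = 1000L, n_genera = 106L,
                             depth_mean = 25000L, depth_dispersion = 0.2,
                             base_concentration = 50,
                             divergence = seq(0, 2, length.out = n_pairs),
                             state_split = 25 / 36,
                             effect_taxa = numeric(0),
                             perturbation = c("logistic_normal", "dirichlet"),
                             seed = 1L) {
  perturbation <- match.arg(perturbation)
  stopifnot(n_pairs >= 1, n_otus >= 2, n_genera >= 1, n_genera <= n_otus,
            depth_mean >= 1, depth_dispersion >= 0, depth_dispersion < 1,
            base_concentration > 0, all(divergence >= 0),
            state_split >= 0, state_split <= 1)
  divergence <- rep_len(divergence, n_pairs)
  structure(list(n_pairs = as.integer(n_pairs), n_otus = as.integer(n_otus),
                 n_genera = as.integer(n_genera),
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 base_concentration = base_concentration,
                 divergence = divergence, state_split = state_split,
                 effect_taxa = effect_taxa, perturbation = perturbation,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a random rooted OTU tree
#'
#' Random bifurcating topology with exponential branch lengths of unit mean
#' (total length grows linearly in the number of leaves); leaves are named
#' `OTU_1 ... OTU_n`.
#'
#' @param n_otus number of leaves (>= 2).
#' @param seed integer seed.
#' @return a rooted [ape::phylo] tree.
#' @export
simulate_tree <- function(n_otus, seed = NULL) {
  if (n_otus < 2) stop("need at least two OTUs for a tree")
  build <- function() {
    tr <- ape::rtree(n_otus, rooted = TRUE, br = stats::rexp,
                     tip.label = paste0("OTU_", seq_len(n_otus)))
    tr$root.edge <- 0
    tr
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Simulate a paired community dataset
#'
#' Draws a global mean profile m ~ Dirichlet(1); per pair a base composition
#' pi ~ Dirichlet(base_concentration * m); the induced member's counts are
#' Multinomial(N, pi). The spontaneous member's composition is the base
#' perturbed on the log scale, pi' = softmax(log pi + eps) with
#' eps ~ Normal(0, sigma^2) per OTU (or a Dirichlet resample when
#' `perturbation = "dirichlet"`), after which any genus-level fold-change
#' effects are applied and the composition renormalised; its counts are
#' Multinomial(N', pi'). OTUs are mapped onto `n_genera` GreenGenes-style
#' lineages (a handful with an unnamed genus label, as real genus summaries
#' contain).
#'
#' @param cfg a [synthetic_config()].
#' @return list with `counts` (OTU x sample integer matrix), `taxonomy`
#'   (named lineage vector), `tree`, `pairing`, and `truth` (per-pair base
#'   and perturbed compositions, L1 divergence, states, applied effects).
#' @export
simulate_paired_tables <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_otus
    otu_ids <- paste0("OTU_", seq_len(n))

    # taxonomy: every genus gets at least one OTU; remaining OTUs land in
    # genera with Dirichlet-skewed probabilities (few big genera, many small)
    genus_of <- integer(n)
    genus_of[seq_len(cfg$n_genera)] <- seq_len(cfg$n_genera)
    if (n > cfg$n_genera) {
      w <- rdirichlet1(rep(0.6, cfg$n_genera))
      genus_of[(cfg$n_genera + 1L):n] <-
        sample.int(cfg$n_genera, n - cfg$n_genera, replace = TRUE, prob = w)
    }
    unnamed <- cfg$n_genera >= 10 & seq_len(cfg$n_genera) %% 10 == 0
    lineages <- paste0("k_Bacteria;p_P", ((seq_len(cfg$n_genera) - 1L) %% 8) + 1L,
                       ";c_C", ((seq_len(cfg$n_genera) - 1L) %% 15) + 1L,
                       ";o_O", ((seq_len(cfg$n_genera) - 1L) %% 30) + 1L,
                       ";f_F", seq_len(cfg$n_genera),
                       ";g_", ifelse(unnamed, "", seq_len(cfg$n_genera)))
    taxonomy <- stats::setNames(lineages[genus_of], otu_ids)

    tree <- simulate_tree(n, seed = child_seed(cfg$seed, "tree"))

    # rank-skewed global mean profile (alpha ~ 1/rank): a handful of OTUs
    # above 1% of all sequences and a long rare tail, as amplicon surveys show
    w <- (1 / seq_len(n)) / sum(1 / seq_len(n))
    m <- rdirichlet1(100 * w)
    n_exac <- round(cfg$state_split * cfg$n_pairs)
    states <- c(rep("stable", cfg$n_pairs - n_exac), rep("exacerbation", n_exac))

    counts <- matrix(0L, n, 2L * cfg$n_pairs)
    rownames(counts) <- otu_ids
    ids_ind <- sprintf("ISS_%02d", seq_len(cfg$n_pairs))
    ids_spo <- sprintf("SSS_%02d", seq_len(cfg$n_pairs))
    colnames(counts) <- c(rbind(ids_ind, ids_spo))

    draw_depth <- function() {
      lo <- (1 - cfg$depth_dispersion) * cfg$depth_mean
      hi <- (1 + cfg$depth_dispersion) * cfg$depth_mean
      as.integer(round(stats::runif(1, lo, hi)))
    }

    pi_list <- vector("list", cfg$n_pairs)
    pi_prime_list <- vector("list", cfg$n_pairs)
    for (j in seq_len(cfg$n_pairs)) {
      pi_j <- rdirichlet1(cfg$base_concentration * m)
      sigma <- cfg$divergence[j]
      if (sigma == 0) {
        pi_p <- pi_j
      } else if (cfg$perturbation == "logistic_normal") {
        lg <- log(pmax(pi_j, 1e-12)) + stats::rnorm(n, 0, sigma)
        lg <- lg - max(lg)
        pi_p <- exp(lg) / sum(exp(lg))
      } else {
        pi_p <- rdirichlet1(pi_j / sigma^2)
      }
      if (length(cfg$effect_taxa)) {
        fold <- rep(1, n)
        for (g in names(cfg$effect_taxa)) {
          hit <- grepl(paste0(";g_", sub("^g_", "", g), "$"), taxonomy)
          fold[hit] <- cfg$effect_taxa[[g]]
        }
        pi_p <- pi_p * fold
        pi_p <- pi_p / sum(pi_p)
      }
      counts[, ids_ind[j]] <- stats::rmultinom(1, draw_depth(), pi_j)
      counts[, ids_spo[j]] <- stats::rmultinom(1, draw_depth(), pi_p)
      pi_list[[j]] <- pi_j
      pi_prime_list[[j]] <- pi_p
    }

    pairing <- data.frame(pair_id = seq_len(cfg$n_pairs),
                          induced_id = ids_ind, spontaneous_id = ids_spo,
                          state = states, stringsAsFactors = FALSE)
    truth <- list(pi = do.call(cbind, pi_list),
                  pi_prime = do.call(cbind, pi_prime_list),
                  l1_divergence = vapply(seq_len(cfg$n_pairs), function(j)
                    sum(abs(pi_list[[j]] - pi_prime_list[[j]])), numeric(1)),
                  divergence = cfg$divergence,
                  states = states,
                  effect_taxa = cfg$effect_taxa)
    list(counts = validate_count_table(counts), taxonomy = taxonomy,
         tree = tree, pairing = pairing, truth = truth)
  })
}
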