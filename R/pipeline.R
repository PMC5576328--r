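#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end concordance analysis with the
#' study's defaults: rarefaction to 18250 sequences/sample for the
#' all-samples and exacerbation analyses and 19743 for the stable-state
#' analysis, a 0.005% rare-OTU floor, a 1% dominance threshold, concordance
#' cut-offs 0.2 (1 - theta) and 0.1 (LOA range), an indicative 0.3 level for
#' Procrustes M^2, alpha 0.01 for Bonferroni-corrected pairwise UniFrac and
#' 0.05 elsewhere.
#'
#' @param rarefy_depths named vector of rarefaction depths per subset.
#' @param min_otu_fraction rare-OTU filter fraction.
#' @param dominant_fraction dominance filter fraction.
#' @param tax_level taxonomic level for collapsing (6 = genus).
#' @param theta_cut,loa_cut concordance cut-offs.
#' @param m2_indicative indicative Procrustes M^2 level.
#' @param alpha_pairwise,alpha alpha levels for pairwise UniFrac and for the
#'   remaining tests.
#' @param unifrac_scope `"paired"` or `"all"` pairwise UniFrac comparisons.
#' @param n_perm_unifrac,n_perm_procrustes,n_perm_anosim,n_perm_alpha
#'   permutation counts per test family.
#' @param otu_level_theta compute the "all" dissimilarity at OTU level
#'   instead of taxon level.
#' @param seed master seed; each stochastic stage consumes a named child
#'   seed derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(rarefy_depths = c(all = 18250L, exacerbation = 18250L,
                                              stable = 19743L),
                            min_otu_fraction = 5e-5,
                            dominant_fraction = 0.01,
                            tax_level = 6L,
                            theta_cut = 0.2, loa_cut = 0.1,
                            m2_indicative = 0.3,
                            alpha_pairwise = 0.01, alpha = 0.05,
                            unifrac_scope = c("paired", "all"),
                            n_perm_unifrac = 1000L,
                            n_perm_procrustes = 1000L,
                            n_perm_anosim = 999L,
                            n_perm_alpha = 999L,
                            otu_level_theta = FALSE,
                            seed = 1L) {
  stopifnot(all(rarefy_depths >= 1), alpha > 0, alpha < 1,
            alpha_pairwise > 0, alpha_pairwise < 1)
  structure(list(rarefy_depths = rarefy_depths,
                 min_otu_fraction = min_otu_fraction,
                 dominant_fraction = dominant_fraction,
                 tax_level = as.integer(tax_level),
                 theta_cut = theta_cut, loa_cut = loa_cut,
                 m2_indicative = m2_indicative,
                 alpha_pairwise = alpha_pairwise, alpha = alpha,
                 unifrac_scope = match.arg(unifrac_scope),
                 n_perm_unifrac = n_perm_unifrac,
                 n_perm_procrustes = n_perm_procrustes,
                 n_perm_anosim = n_perm_anosim,
                 n_perm_alpha = n_perm_alpha,
                 otu_level_theta = otu_level_theta,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full paired-concordance analysis
#'
#' Executes, in order: rare-OTU filtering; per-pair Yue-Clayton and
#' Bland-Altman statistics (all and dominant OTU sets) with concordance
#' classification; group-level Yue-Clayton dissimilarities per disease-state
#' subset; rarefaction per subset followed by per-taxon G tests; alpha
#' diversity with permutation group tests; UniFrac distance matrices
#' (unweighted and raw weighted) with Monte-Carlo pairwise significance and
#' Bonferroni correction; PCoA of the weighted UniFrac distances; Procrustes
#' superimposition of the induced vs spontaneous configurations (axes 1-3,
#' Monte-Carlo); and ANOSIM by sample type per subset.
#'
#' @param table OTU count table.
#' @param tax taxonomy map.
#' @param tree rooted phylogenetic tree.
#' @param pairing sample pairing table.
#' @param config a [pipeline_config()].
#' @return a `mbpairs_result` list bundling every stage's output plus a log
#'   of filtering and seeding decisions.
#' @export
run_pipeline <- function(table, tax, tree, pairing, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  pairing <- validate_pairing(pairing, table)
  if (nrow(pairing) == 0L) stop("empty pairing")
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  note("master seed: ", config$seed)

  n0 <- nrow(table)
  table <- filter_rare(table, config$min_otu_fraction)
  note("rare-OTU filter (", config$min_otu_fraction, "): removed ",
       n0 - nrow(table), " of ", n0, " OTUs")

  subsets <- intersect(c("all", "exacerbation", "stable"),
                       c("all", unique(pairing$state)))

  # branch A: taxonomic concordance on unrarefied relative abundances
  pairs <- classify_pairs(
    pair_concordance(table, tax, pairing, level = config$tax_level,
                     dominant_fraction = config$dominant_fraction,
                     otu_level = config$otu_level_theta),
    theta_cut = config$theta_cut, loa_cut = config$loa_cut)
  group_theta <- do.call(rbind, lapply(subsets, function(s) {
    data.frame(subset = s,
               otu_set = c("dominant", "all"),
               one_minus_theta = c(
                 group_mean_dissimilarity(table, tax, pairing, subset = s,
                                          otu_set = "dominant",
                                          level = config$tax_level,
                                          dominant_fraction = config$dominant_fraction),
                 group_mean_dissimilarity(table, tax, pairing, subset = s,
                                          otu_set = "all",
                                          level = config$tax_level)),
               stringsAsFactors = FALSE)
  }))

  # per-subset rarefied analyses: G tests and alpha diversity
  g_tests <- list(); alpha_tab <- list(); alpha_tests <- list()
  for (s in subsets) {
    sub <- subset_pairing(pairing, s)
    ids <- c(sub$induced_id, sub$spontaneous_id)
    depth <- config$rarefy_depths[[s]] %||% config$rarefy_depths[["all"]]
    rar <- rarefy(table[, ids, drop = FALSE], depth,
                  seed = child_seed(config$seed, paste0("rarefy_", s)))
    note("subset ", s, ": rarefied ", ncol(rar), "/", length(ids),
         " samples to depth ", depth)
    kept <- colnames(rar)
    type <- stats::setNames(ifelse(kept %in% sub$induced_id, "induced", "spontaneous"),
                            kept)
    taxa <- collapse_taxonomy(rar, tax, config$tax_level)
    g_tests[[s]] <- taxon_g_test(taxa, type)
    a <- alpha_diversity(rar, tree)
    a$type <- unname(type[a$sample_id])
    alpha_tab[[s]] <- a
    alpha_tests[[s]] <- do.call(rbind, lapply(
      c("observed_otus", "chao1", "faith_pd"), function(metric) {
        r <- alpha_group_test(a[[metric]][a$type == "induced"],
                              a[[metric]][a$type == "spontaneous"],
                              n_perm = config$n_perm_alpha,
                              seed = child_seed(config$seed,
                                                paste0("alpha_", s, "_", metric)))
        data.frame(subset = s, metric = metric,
                   mean_induced = mean(a[[metric]][a$type == "induced"]),
                   mean_spontaneous = mean(a[[metric]][a$type == "spontaneous"]),
                   t_statistic = r$t_statistic, p = r$p,
                   stringsAsFactors = FALSE)
      }))
  }

  # beta diversity on the all-samples rarefied table
  depth_all <- config$rarefy_depths[["all"]]
  rar_all <- rarefy(table, depth_all, seed = child_seed(config$seed, "rarefy_all"))
  pairing_beta <- pairing[pairing$induced_id %in% colnames(rar_all) &
                            pairing$spontaneous_id %in% colnames(rar_all), ,
                          drop = FALSE]
  dm_wuf <- unifrac_matrix(rar_all, tree, metric = "weighted")
  dm_uwuf <- unifrac_matrix(rar_all, tree, metric = "unweighted")
  pairwise <- unifrac_pairwise_tests(rar_all, tree, pairing = pairing_beta,
                                     scope = config$unifrac_scope,
                                     metric = "weighted",
                                     n_perm = config$n_perm_unifrac,
                                     seed = child_seed(config$seed, "unifrac_perm"))
  note("pairwise weighted UniFrac: ", nrow(pairwise), " comparisons, n_perm = ",
       config$n_perm_unifrac)

  # ordination: PCoA of WUF, Procrustes of method configurations, ANOSIM
  ord <- pcoa(dm_wuf)
  proc <- procrustes_monte_carlo(
    dm_wuf[pairing_beta$induced_id, pairing_beta$induced_id],
    dm_wuf[pairing_beta$spontaneous_id, pairing_beta$spontaneous_id],
    axes = 3L, n_perm = config$n_perm_procrustes,
    seed = child_seed(config$seed, "procrustes"))
  type_all <- stats::setNames(
    ifelse(colnames(rar_all) %in% pairing$induced_id, "induced", "spontaneous"),
    colnames(rar_all))
  anosim_res <- do.call(rbind, lapply(subsets, function(s) {
    sub <- subset_pairing(pairing_beta, s)
    ids <- intersect(c(sub$induced_id, sub$spontaneous_id), colnames(rar_all))
    out <- lapply(list(wuf = dm_wuf, uwuf = dm_uwuf), function(dm) {
      anosim(dm[ids, ids], type_all[ids], n_perm = config$n_perm_anosim,
             seed = child_seed(config$seed, paste0("anosim_", s)))
    })
    data.frame(subset = s, metric = c("wuf", "uwuf"),
               R = c(out$wuf$R, out$uwuf$R), p = c(out$wuf$p, out$uwuf$p),
               stringsAsFactors = FALSE)
  }))

  structure(list(pairs = pairs, group_theta = group_theta,
                 g_tests = g_tests, alpha = alpha_tab,
                 alpha_tests = alpha_tests,
                 dm_wuf = dm_wuf, dm_uwuf = dm_uwuf,
                 pairwise_unifrac = pairwise,
                 pcoa = ord, procrustes = proc, anosim = anosim_res,
                 config = config, log = log_lines),
            class = "mbpairs_result")
}
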