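#!/usr/bin/env Rscript
# Step 3: diversity. Rarefaction per disease-state subset, per-taxon G tests
# with Bonferroni correction, alpha diversity (observed OTUs, Chao1, Faith
# PD) with permutation t-tests, and Monte-Carlo weighted-UniFrac
# significance for each matched pair.

suppressMessages(library(mbpairs))

ind <- "results/simulated"
out <- "results/diversity"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20170830L

counts <- filter_rare(read_count_table(file.path(ind, "otu_table.tsv")), 5e-5)
tax <- read_taxonomy(file.path(ind, "taxonomy.tsv"))
tree <- read_newick(file.path(ind, "tree.nwk"))
pairing <- read_pairing(file.path(ind, "pairing.tsv"))

depths <- c(all = 18250L, exacerbation = 18250L, stable = 19743L)
for (sub in names(depths)) {
  keep <- if (sub == "all") pairing else pairing[pairing$state == sub, ]
  ids <- c(keep$induced_id, keep$spontaneous_id)
  rar <- rarefy(counts[, ids], depths[[sub]],
                seed = child_seed(seed, paste0("rarefy_", sub)))
  type <- setNames(ifelse(colnames(rar) %in% keep$induced_id,
                          "induced", "spontaneous"), colnames(rar))
  gt <- taxon_g_test(collapse_taxonomy(rar, tax, 6L), type)
  utils::write.table(gt, file.path(out, paste0("g_tests_", sub, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sub, ": ", sum(gt$p_bonferroni < 0.05), " of ", nrow(gt),
      " taxa differ between methods (Bonferroni p < 0.05)\n", sep = "")

  a <- alpha_diversity(rar, tree)
  a$type <- unname(type[a$sample_id])
  utils::write.table(a, file.path(out, paste0("alpha_", sub, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (metric in c("observed_otus", "chao1", "faith_pd")) {
    r <- alpha_group_test(a[[metric]][a$type == "induced"],
                          a[[metric]][a$type == "spontaneous"],
                          n_perm = 999,
                          seed = child_seed(seed, paste0(sub, metric)))
    cat(sprintf("  %-13s induced %8.1f  spontaneous %8.1f  p = %.3f\n", metric,
                mean(a[[metric]][a$type == "induced"]),
                mean(a[[metric]][a$type == "spontaneous"]), r$p))
  }
}

rar_all <- rarefy(counts, depths[["all"]], seed = child_seed(seed, "rarefy_all"))
# enough permutations that the minimum attainable Bonferroni-corrected
# p-value (n_pairs / (n_perm + 1)) clears the 0.01 level
pw <- unifrac_pairwise_tests(rar_all, tree, pairing, scope = "paired",
                             metric = "weighted", n_perm = 3999,
                             seed = child_seed(seed, "wuf_pairs"))
utils::write.table(pw, file.path(out, "pairwise_wuf.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("\nPairwise weighted UniFrac: ", sum(pw$p_bonferroni < 0.01), " of ",
    nrow(pw), " pairs differ (Bonferroni p < 0.01)\n", sep = "")
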