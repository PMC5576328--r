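#' Write the analysis report
#'
#' Writes a machine-readable per-pair table (`pairs.tsv`, full stored
#' precision so re-reading reproduces every number) plus supporting tables
#' and a short human-readable summary (`report.md`) under `dir`.
#'
#' @param results an `mbpairs_result` from [run_pipeline()], or any data
#'   frame shaped like its `pairs` component.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create report directory ", dir)
  tsv <- function(df, name) {
    path <- file.path(dir, name)
    df <- as.data.frame(df)
    # %.17g survives a write/read round trip bit-exactly
    df[] <- lapply(df, function(col)
      if (is.double(col)) sprintf("%.17g", col) else col)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  if (is.data.frame(results)) {
    return(invisible(tsv(results, "pairs.tsv")))
  }
  stopifnot(inherits(results, "mbpairs_result"))
  paths <- c(
    tsv(results$pairs, "pairs.tsv"),
    tsv(results$group_theta, "group_theta.tsv"),
    tsv(do.call(rbind, Map(cbind, subset = names(results$g_tests),
                           results$g_tests)), "g_tests.tsv"),
    tsv(do.call(rbind, results$alpha_tests), "alpha_tests.tsv"),
    tsv(do.call(rbind, Map(cbind, subset = names(results$alpha),
                           results$alpha)), "alpha_diversity.tsv"),
    tsv(results$pairwise_unifrac, "pairwise_unifrac.tsv"),
    tsv(results$anosim, "anosim.tsv"))
  dm_out <- data.frame(sample_id = rownames(results$dm_wuf), results$dm_wuf,
                       check.names = FALSE)
  paths <- c(paths, tsv(dm_out, "wuf_distances.tsv"))

  s <- attr(results$pairs, "summary")
  cfg <- results$config
  md <- c(
    "# Paired sputum concordance report", "",
    paste0("Pairs analysed: ", nrow(results$pairs)),
    paste0("1 - theta cut-off: ", cfg$theta_cut,
           "; LOA range cut-off: ", cfg$loa_cut), "",
    "## Discordant pairs (strict > cut-off)", "",
    paste(utils::capture.output(print(s, row.names = FALSE)), collapse = "\n"), "",
    "## Group-level Yue-Clayton dissimilarity", "",
    paste(utils::capture.output(print(results$group_theta, row.names = FALSE)),
          collapse = "\n"), "",
    paste0("Procrustes M^2 (PC1-3): ",
           formatC(results$procrustes$m_squared, digits = 4, format = "f"),
           " (Monte-Carlo p = ", results$procrustes$p_monte_carlo,
           ", indicative level ", cfg$m2_indicative, ")"), "",
    paste0("Pairwise weighted UniFrac: ",
           sum(results$pairwise_unifrac$p_bonferroni < cfg$alpha_pairwise),
           " of ", nrow(results$pairwise_unifrac),
           " comparisons significant at Bonferroni-corrected p < ",
           cfg$alpha_pairwise), "",
    "## Log", "", results$log)
  md_path <- file.path(dir, "report.md")
  writeLines(md, md_path)
  invisible(c(paths, md_path))
}

#' Re-read a per-pair report table
#' @param path a `pairs.tsv` written by [write_report()].
#' @return data frame with the stored per-pair statistics.
#' @export
read_report_pairs <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
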