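#' Convert counts to within-sample relative abundances
#'
#' @param table count table (OTU x sample matrix).
#' @param percent if `TRUE`, return percentages (columns sum to 100) instead
#'   of proportions.
#' @return numeric matrix of the same shape; all-zero samples stay zero and
#'   are recorded in attribute `"empty_samples"`.
#' @export
to_relative <- function(table, percent = FALSE) {
  totals <- colSums(table)
  empty <- totals == 0
  totals[empty] <- 1
  rel <- sweep(table, 2L, totals, "/")
  if (percent) rel <- rel * 100
  attr(rel, "empty_samples") <- colnames(table)[empty]
  rel
}

# Shared threshold filter: retain OTU i iff its table-wide total is at least
# min_fraction x grand total (>= convention: an OTU exactly at the cut stays).
filter_by_fraction <- function(table, min_fraction, what) {
  if (min_fraction < 0 || min_fraction >= 1)
    stop("min_fraction must be in [0, 1)")
  grand <- sum(as.numeric(table))
  keep <- rowSums(table) >= min_fraction * grand
  if (!any(keep))
    warning("no OTUs pass the ", what, " filter at fraction ", min_fraction)
  table[keep, , drop = FALSE]
}

#' Remove rare OTUs
#'
#' Drops OTUs holding less than `min_fraction` of the table's total
#' sequences. The default 5e-5 is the conventional 0.005% abundance floor
#' applied to amplicon OTU tables before analysis.
#'
#' @param table count table.
#' @param min_fraction minimum fraction of the grand total (default 5e-5).
#' @return filtered count table; sample set unchanged.
#' @export
filter_rare <- function(table, min_fraction = 5e-5) {
  filter_by_fraction(table, min_fraction, "rare-OTU")
}

#' Keep only dominant OTUs
#'
#' Retains OTUs each holding at least `min_fraction` (default 1%) of all
#' sequences, the definition used for the "dominating taxa" view of the
#' pairwise comparisons.
#'
#' @inheritParams filter_rare
#' @return filtered count table.
#' @export
filter_dominant <- function(table, min_fraction = 0.01) {
  filter_by_fraction(table, min_fraction, "dominant-OTU")
}

#' Collapse an OTU table to a taxonomic level
#'
#' Sums counts of OTUs whose lineages agree through `level` ranks (default
#' level 6, genus). OTUs without a taxonomy entry are pooled under
#' `"Unassigned"`. Per-sample totals are conserved exactly.
#'
#' @param table count table.
#' @param tax named character vector of lineage strings (see [read_taxonomy()]).
#' @param level rank depth 1-7.
#' @return taxon x sample count matrix; row names are truncated lineages.
#' @export
collapse_taxonomy <- function(table, tax, level = 6L) {
  if (level < 1L || level > 7L) stop("taxonomic level must be in 1-7")
  lineages <- tax[rownames(table)]
  missing <- is.na(lineages)
  labels <- character(nrow(table))
  labels[missing] <- "Unassigned"
  if (any(!missing)) labels[!missing] <- taxon_label(lineages[!missing], level)
  out <- rowsum(table, group = labels, reorder = TRUE)
  storage.mode(out) <- "integer"
  out
}

#' Rarefy a count table to even depth
#'
#' Random subsampling without replacement (multivariate hypergeometric) of
#' each sample to exactly `depth` sequences. Samples with fewer than `depth`
#' sequences are dropped with a message listing them.
#'
#' @param table count table.
#' @param depth target sequences per sample (>= 1).
#' @param seed integer seed; identical seed gives identical output.
#' @return rarefied count table whose columns all sum to `depth`.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  if (depth < 1) stop("rarefaction depth must be >= 1")
  totals <- colSums(table)
  shallow <- totals < depth
  if (all(shallow)) stop("all samples are shallower than depth ", depth)
  if (any(shallow))
    message("dropping ", sum(shallow), " sample(s) below depth ", depth, ": ",
            paste(colnames(table)[shallow], collapse = ", "))
  kept <- table[, !shallow, drop = FALSE]
  # vegan warns when the smallest non-zero count exceeds 1 (a heuristic for
  # pre-normalised input); our validated tables are raw counts, so muffle it
  draw <- function() suppressWarnings(t(vegan::rrarefy(t(kept), depth)))
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  storage.mode(out) <- "integer"
  out
}
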