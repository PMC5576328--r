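#' Parse a GreenGenes-style lineage string
#'
#' Splits on `;`, trims whitespace, and normalises rank prefixes so that both
#' `g__Moraxella` (GreenGenes files) and `g_Moraxella` (as printed in
#' genus-level summaries) become `g_Moraxella`. Empty rank labels such as an
#' unnamed genus (`f_Gemellaceae;g_`) are preserved as the bare prefix.
#'
#' @param lineage character vector of lineage strings.
#' @return a list of character vectors, one rank label per element (at most 7
#'   ranks, kingdom through species).
#' @export
parse_lineage <- function(lineage) {
  lapply(strsplit(as.character(lineage), ";", fixed = TRUE), function(ranks) {
    ranks <- trimws(ranks)
    if (length(ranks) < 1L || length(ranks) > 7L)
      stop("lineage must have 1-7 ranks: ", paste(ranks, collapse = ";"))
    sub("^([a-z])__", "\\1_", ranks)
  })
}

#' Truncate lineages to a taxonomic level
#'
#' @param lineage character vector of lineage strings.
#' @param level rank depth 1-7 (6 = genus, the level the concordance analysis
#'   is run at).
#' @return character vector of taxon labels, lineages truncated at `level`
#'   and re-joined with `;`.
#' @export
taxon_label <- function(lineage, level = 6L) {
  if (level < 1L || level > 7L) stop("taxonomic level must be in 1-7")
  vapply(parse_lineage(lineage), function(r) {
    paste(r[seq_len(min(level, length(r)))], collapse = ";")
  }, character(1))
}

#' Read an OTU taxonomy map
#'
#' Two-column tab-separated file: OTU id, lineage string. Extra columns
#' (e.g. an assignment confidence) are ignored.
#'
#' @param path file path.
#' @return named character vector, OTU id -> lineage string.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2L) stop("taxonomy file needs two columns: otu id, lineage")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate OTU ids in taxonomy file")
  tax <- as.character(df[[2L]])
  invisible(parse_lineage(tax))  # validates rank counts
  stats::setNames(tax, ids)
}

#' Write an OTU taxonomy map
#' @param tax named character vector, OTU id -> lineage string.
#' @param path destination file.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(data.frame(names(tax), unname(tax)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
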