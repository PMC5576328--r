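#' Read a sample-pairing table
#'
#' Tab-separated file with columns `pair_id`, `induced_id`, `spontaneous_id`,
#' `state`; `state` must be `stable` or `exacerbation`. Each pair matches one
#' induced-sputum sample with the spontaneous-sputum sample collected at the
#' same consultation.
#'
#' @param path file path.
#' @return data frame with those four columns.
#' @export
read_pairing <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  validate_pairing(df)
}

#' Validate a sample-pairing table
#'
#' @param pairing data frame with columns `pair_id`, `induced_id`,
#'   `spontaneous_id`, `state`.
#' @param table optional count table; if given, every sample id must be one
#'   of its columns.
#' @return the validated pairing, with `state` as character.
#' @export
validate_pairing <- function(pairing, table = NULL) {
  need <- c("pair_id", "induced_id", "spontaneous_id", "state")
  if (!all(need %in% names(pairing)))
    stop("pairing table must have columns: ", paste(need, collapse = ", "))
  pairing <- as.data.frame(pairing)[need]
  pairing$state <- as.character(pairing$state)
  if (nrow(pairing) > 0L) {
    if (!all(pairing$state %in% c("stable", "exacerbation")))
      stop("unknown state token; expected 'stable' or 'exacerbation'")
    if (any(pairing$induced_id == pairing$spontaneous_id))
      stop("a pair's two members must be distinct samples")
    all_ids <- c(pairing$induced_id, pairing$spontaneous_id)
    if (anyDuplicated(all_ids))
      stop("sample listed in more than one pair: ",
           paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
    if (anyDuplicated(pairing$pair_id)) stop("duplicate pair_id")
    if (!is.null(table)) {
      missing <- setdiff(all_ids, colnames(table))
      if (length(missing))
        stop("paired samples absent from count table: ",
             paste(missing, collapse = ", "))
    }
  }
  pairing
}

#' Write a sample-pairing table
#' @param pairing pairing data frame.
#' @param path destination file.
#' @export
write_pairing <- function(pairing, path) {
  utils::write.table(pairing, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Restrict a pairing to a disease-state subset.
subset_pairing <- function(pairing, subset = c("all", "exacerbation", "stable")) {
  subset <- match.arg(subset)
  out <- if (subset == "all") pairing else pairing[pairing$state == subset, , drop = FALSE]
  if (nrow(out) == 0L) stop("no pairs in subset '", subset, "'")
  out
}
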