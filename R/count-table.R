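#' Validate an OTU count table
#'
#' A count table is an integer matrix of sequence counts with OTUs as rows
#' and samples as columns; row and column names are the OTU and sample
#' identifiers. This is the central object every analysis stage transforms.
#'
#' @param x matrix to validate.
#' @return `x`, invisibly, with integer storage mode.
#' @export
validate_count_table <- function(x) {
  if (!is.matrix(x)) stop("count table must be a matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count table must carry OTU row names and sample column names")
  if (anyDuplicated(rownames(x))) stop("duplicate OTU ids in count table")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids in count table")
  if (!is.numeric(x) || anyNA(x)) stop("count table cells must be numeric and non-missing")
  if (any(x < 0)) stop("count table contains negative counts")
  if (any(x != round(x))) stop("count table contains non-integral counts")
  storage.mode(x) <- "integer"
  invisible(x)
}

#' Read an OTU count table
#'
#' Reads either a tab-separated matrix (first column OTU ids, header row
#' sample ids; a leading `#OTU ID` header and QIIME-style comment lines are
#' tolerated) or a BIOM 1.0 JSON file, sparse or dense.
#'
#' @param path file path.
#' @param dialect `"tsv"`, `"biom_json"`, or `"auto"` (default: sniff; files
#'   starting with `{` are treated as BIOM JSON).
#' @return a validated count table (integer matrix, OTUs x samples).
#' @export
read_count_table <- function(path, dialect = c("auto", "tsv", "biom_json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "auto") {
    first <- substr(trimws(suppressWarnings(readLines(path, n = 1L))), 1L, 1L)
    dialect <- if (identical(first, "{")) "biom_json" else "tsv"
  }
  if (dialect == "biom_json") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
  } else {
    lines <- readLines(path)
    keep <- !grepl("^#", lines) | grepl("^#OTU", lines)
    if (!any(keep)) stop("no table content in ", path)
    con <- textConnection(lines[keep])
    on.exit(close(con))
    df <- utils::read.delim(con, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "")
    if (ncol(df) < 2L) stop("tsv count table needs an id column and >=1 sample")
    ids <- as.character(df[[1L]])
    cn <- names(df)[-1L]           # data-frame subsetting uniquifies names
    m <- as.matrix(df[-1L])
    if (!is.numeric(m)) stop("non-numeric cell in count table ", path)
    dimnames(m) <- list(ids, cn)
  }
  validate_count_table(m)
  storage.mode(m) <- "integer"
  m
}

#' Write an OTU count table
#'
#' @param x count table matrix.
#' @param path destination file.
#' @param dialect `"tsv"` (default) or `"biom_json"`.
#' @export
write_count_table <- function(x, path, dialect = c("tsv", "biom_json")) {
  dialect <- match.arg(dialect)
  validate_count_table(x)
  if (dialect == "biom_json") {
    biomformat::write_biom(biomformat::make_biom(x), path)
  } else {
    df <- data.frame(`#OTU ID` = rownames(x), x, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
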