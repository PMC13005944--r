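#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV file into a samples x proteins numeric matrix. The header
#' row carries protein ids and the first column sample ids; files stored the
#' other way round are handled with `orientation = "proteins_in_rows"`.
#'
#' @param path File path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param orientation `"samples_in_rows"` (default) or `"proteins_in_rows"`.
#' @param missing_tokens Character values parsed as missing (besides literal
#'   `NA`); defaults to the empty string and `"NA"`.
#' @return Numeric matrix with sample row names and protein column names;
#'   missing cells are `NA`, never silently zero.
#' @export
read_expression <- function(path,
                            orientation = c("samples_in_rows", "proteins_in_rows"),
                            missing_tokens = c("", "NA")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          na.strings = missing_tokens, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate row ids in ", path)
  if (anyDuplicated(names(df)[-1])) stop("duplicate column ids in ", path)
  body <- as.matrix(df[, -1, drop = FALSE])
  bad <- !is.na(body) & is.na(suppressWarnings(as.numeric(body)))
  if (any(bad))
    stop("non-numeric cell(s) in ", path, ", e.g. '", body[which(bad)[1]], "'")
  m <- matrix(as.numeric(body), nrow = nrow(body),
              dimnames = list(ids, colnames(body)))
  if (orientation == "proteins_in_rows") m <- t(m)
  m
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression()]: header of protein ids, first column of
#' sample ids, `NA` for missing cells.
#'
#' @param m Numeric matrix, samples x proteins.
#' @param path Output path; `.csv` writes commas, otherwise tabs.
#' @export
write_expression <- function(m, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a clinical table
#'
#' Expects columns `sample_id`, `time` (months) and `event` (0/1); an optional
#' `subtype` column is carried through. Rows with missing time are dropped
#' with a message; negative times are an error.
#'
#' @param path File path (`.csv` comma-separated, otherwise tab-separated).
#' @param endpoint Endpoint this table describes, `"OS"` or `"RFS"`.
#' @return Data frame with attribute `endpoint`.
#' @export
read_clinical <- function(path, endpoint = c("OS", "RFS")) {
  endpoint <- match.arg(endpoint)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = c("", "NA"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "time", "event") %in% names(df)))
  df$time <- as.numeric(df$time)
  if (any(df$time < 0, na.rm = TRUE)) stop("negative survival time in ", path)
  n_missing <- sum(is.na(df$time))
  if (n_missing) {
    message("read_clinical: dropping ", n_missing, " row(s) with missing time")
    df <- df[!is.na(df$time), , drop = FALSE]
  }
  ev <- df$event
  if (is.character(ev)) ev <- as.numeric(ev)
  if (!all(ev %in% c(0, 1))) stop("event column must be coded 0/1")
  df$event <- as.integer(ev)
  attr(df, "endpoint") <- endpoint
  df
}

#' Read a signature protein list
#'
#' One identifier per line; blank lines and duplicate ids are dropped.
#'
#' @param path File path.
#' @return Character vector of ids.
#' @export
read_signature <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  unique(ids[nzchar(ids)])
}

#' Read gene sets in GMT format
#'
#' Thin wrapper over [fgsea::gmtPathways()] (tab-separated: name, description,
#' members).
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)
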