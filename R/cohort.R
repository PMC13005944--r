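#' Assemble a patient cohort
#'
#' A cohort bundles an expression matrix (samples in rows, proteins in
#' columns), one clinical table per survival endpoint, and optionally a
#' per-sample subtype label vector. It is the unit every training, simulation
#' and evaluation function in this package operates on.
#'
#' @param expr Numeric matrix, samples x proteins, with unique row names
#'   (sample ids) and column names (protein ids). Missing values allowed.
#' @param clinical Named list of clinical data frames, one per endpoint
#'   (e.g. `"OS"`, `"RFS"`), each with columns `sample_id`, `time` (months,
#'   non-negative) and `event` (0 = censored, 1 = event observed).
#' @param labels Optional integer vector of subtype labels in `1..k`, named by
#'   sample id, covering every sample in `expr`. Smaller label = better
#'   prognosis by convention.
#' @param preprocessed Logical flag recording whether [preprocess_pair()] has
#'   been applied; interpretation helpers use it to warn when weights are
#'   compared across proteins on unstandardised scales.
#'
#' @return An object of class `srps_cohort`.
#' @export
cohort <- function(expr, clinical = list(), labels = NULL, preprocessed = FALSE) {
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must have sample row names and protein column names")
  if (anyDuplicated(rownames(expr))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(expr))) stop("duplicate protein ids")
  if (length(clinical)) {
    if (is.null(names(clinical)) || any(!nzchar(names(clinical))))
      stop("clinical tables must be named by endpoint (e.g. OS, RFS)")
    for (ep in names(clinical)) {
      cl <- clinical[[ep]]
      stopifnot(all(c("sample_id", "time", "event") %in% names(cl)))
      if (any(cl$time < 0, na.rm = TRUE)) stop("negative survival time in endpoint ", ep)
      extra <- setdiff(cl$sample_id, rownames(expr))
      if (length(extra))
        stop("clinical sample ids absent from expression matrix: ",
             paste(utils::head(extra, 3), collapse = ", "))
    }
  }
  if (!is.null(labels)) {
    if (is.null(names(labels))) {
      if (length(labels) != nrow(expr))
        stop("unnamed labels must have one entry per sample")
      names(labels) <- rownames(expr)
    }
    if (!all(rownames(expr) %in% names(labels)))
      stop("labels must cover every sample")
    labels <- as.integer(labels[rownames(expr)])
    names(labels) <- rownames(expr)
    if (any(is.na(labels)) || any(labels < 1L)) stop("labels must be integers >= 1")
  }
  structure(
    list(expr = expr, clinical = clinical, labels = labels,
         preprocessed = isTRUE(preprocessed)),
    class = "srps_cohort"
  )
}

#' @export
print.srps_cohort <- function(x, ...) {
  cat(sprintf("srps_cohort: %d samples x %d proteins\n", nrow(x$expr), ncol(x$expr)))
  cat(sprintf("  endpoints: %s\n",
              if (length(x$clinical)) paste(names(x$clinical), collapse = ", ") else "none"))
  cat(sprintf("  labels: %s\n",
              if (is.null(x$labels)) "none"
              else paste0(length(unique(x$labels)), " subtypes")))
  cat(sprintf("  preprocessed: %s\n", x$preprocessed))
  invisible(x)
}

#' Number of samples in a cohort
#' @param x An `srps_cohort`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) nrow(x$expr)

#' Subset a cohort by sample
#'
#' Keeps the expression rows, clinical records and labels of the selected
#' samples, in the given order.
#'
#' @param x An `srps_cohort`.
#' @param samples Character vector of sample ids or integer/logical row index.
#' @return A new `srps_cohort`.
#' @export
cohort_subset <- function(x, samples) {
  ids <- if (is.character(samples)) samples else rownames(x$expr)[samples]
  expr <- x$expr[ids, , drop = FALSE]
  clinical <- lapply(x$clinical, function(cl) cl[cl$sample_id %in% ids, , drop = FALSE])
  labels <- if (!is.null(x$labels)) x$labels[ids] else NULL
  cohort(expr, clinical, labels, preprocessed = x$preprocessed)
}

#' Survival vectors for one endpoint, aligned to the expression rows
#'
#' @param x An `srps_cohort`.
#' @param endpoint Endpoint name; defaults to the first clinical table.
#' @return List with `time`, `event` and `sample_id`, ordered like the rows of
#'   `x$expr` (samples without a clinical record are dropped).
#' @export
cohort_survival <- function(x, endpoint = NULL) {
  if (!length(x$clinical)) stop("cohort has no clinical tables")
  if (is.null(endpoint)) endpoint <- names(x$clinical)[1]
  cl <- x$clinical[[endpoint]]
  if (is.null(cl)) stop("no clinical table for endpoint ", endpoint)
  ids <- intersect(rownames(x$expr), cl$sample_id)
  cl <- cl[match(ids, cl$sample_id), , drop = FALSE]
  list(time = cl$time, event = cl$event, sample_id = ids)
}
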