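#' Delta-weight subtype significance score
#'
#' For a bias-free linear softmax classifier with weight matrix `theta`
#' (subtypes x proteins), the score of protein `i` for subtype `a` is
#' `theta[a, i] - mean(theta[b, i] for b != a)`: how strongly the protein
#' pushes a call toward subtype `a` relative to the competition. Because the
#' deterministic prediction depends only on logit differences, the score is
#' invariant to adding any per-protein constant to all subtypes, and the
#' scores of one protein sum to zero across subtypes.
#'
#' @param theta k x d weight matrix with protein column names.
#' @return Object of class `delta_weight_table`: list with `delta` (k x d),
#'   `proteins` and `n_models_averaged`.
#' @export
delta_weight <- function(theta) {
  k <- nrow(theta)
  if (is.null(k) || k < 2) stop("need a k x d weight matrix with k >= 2")
  delta <- theta - (matrix(colSums(theta), k, ncol(theta), byrow = TRUE) - theta) / (k - 1)
  structure(list(delta = delta, proteins = colnames(theta), n_models_averaged = 1L),
            class = "delta_weight_table")
}

#' @export
print.delta_weight_table <- function(x, ...) {
  cat(sprintf("delta_weight_table: %d subtypes x %d proteins (average of %d model(s))\n",
              nrow(x$delta), ncol(x$delta), x$n_models_averaged))
  invisible(x)
}

#' Average delta-weight tables over an ensemble of models
#'
#' Element-wise mean across models (typically the 25 classifiers of a 5x5
#' repeated cross-validation), recorded in `n_models_averaged`. Averaging
#' damps the influence of random initialization on individual weights.
#'
#' @param tables List of `delta_weight_table`s over identical protein sets.
#' @return A `delta_weight_table`.
#' @export
aggregate_delta_weight <- function(tables) {
  stopifnot(length(tables) >= 1)
  ref <- tables[[1]]$proteins
  for (tb in tables)
    if (!identical(tb$proteins, ref)) stop("tables disagree on the protein set")
  delta <- Reduce(`+`, lapply(tables, `[[`, "delta")) / length(tables)
  n <- sum(vapply(tables, `[[`, integer(1), "n_models_averaged"))
  structure(list(delta = delta, proteins = ref, n_models_averaged = n),
            class = "delta_weight_table")
}

#' Rank proteins by delta weight for one subtype
#'
#' @param table A `delta_weight_table`.
#' @param subtype Subtype index.
#' @param top_n How many proteins to return (clipped at d with a warning).
#' @return Character vector of protein ids, descending score; exact ties break
#'   lexicographically.
#' @export
rank_proteins <- function(table, subtype, top_n = 30) {
  stopifnot(subtype >= 1, subtype <= nrow(table$delta))
  d <- ncol(table$delta)
  if (top_n > d) {
    warning("top_n clipped from ", top_n, " to ", d)
    top_n <- d
  }
  v <- table$delta[subtype, ]
  ord <- order(-v, table$proteins)
  table$proteins[ord][seq_len(top_n)]
}

#' Stability of a protein ranking across checkpoints or ensemble sizes
#'
#' For a sequence of delta-weight tables (training checkpoints, or averages
#' over growing model subsets), reports per step the overlap fraction of its
#' top-`top_n` list with the final table's.
#'
#' @param tables List of >= 2 `delta_weight_table`s.
#' @param subtype Subtype index.
#' @param top_n Ranking depth (default 10).
#' @return Numeric vector of overlap fractions, one per table; the last is 1.
#' @export
ranking_stability <- function(tables, subtype, top_n = 10) {
  stopifnot(length(tables) >= 2)
  final <- rank_proteins(tables[[length(tables)]], subtype, top_n)
  vapply(tables, function(tb)
    length(intersect(rank_proteins(tb, subtype, top_n), final)) / top_n,
    numeric(1))
}

#' Write a delta-weight table as TSV
#'
#' Long format: protein, subtype, delta_weight, rank (within subtype,
#' descending score).
#'
#' @param table A `delta_weight_table`.
#' @param path Output path.
#' @export
write_delta_weight <- function(table, path) {
  k <- nrow(table$delta)
  rows <- do.call(rbind, lapply(seq_len(k), function(s) {
    v <- table$delta[s, ]
    data.frame(protein = table$proteins, subtype = s, delta_weight = v,
               rank = rank(-v, ties.method = "min"))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
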