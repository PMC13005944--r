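#' Single-sample gene-set enrichment scores
#'
#' Rank-weighted running-sum enrichment per sample and gene set: genes are
#' ranked by expression within the sample, the walk down the ranking
#' accumulates in-set ranks raised to `alpha` against the flat out-of-set
#' ECDF, and the score is the sum of the difference of the two empirical
#' CDFs. Gene sets overlapping fewer than `min_overlap` measured genes are
#' dropped with a message.
#'
#' @param expr Samples x genes matrix (quantile-normalized expression).
#' @param gene_sets Named list of character vectors.
#' @param alpha Rank-weight exponent (default 0.25).
#' @param min_overlap Minimum overlapping genes per set (default 10).
#' @return Samples x sets score matrix.
#' @export
ssgsea_scores <- function(expr, gene_sets, alpha = 0.25, min_overlap = 10) {
  genes <- colnames(expr)
  sets <- lapply(gene_sets, function(s) which(genes %in% s))
  keep <- vapply(sets, length, integer(1)) >= min_overlap
  if (!all(keep))
    message("ssgsea_scores: dropping ", sum(!keep),
            " gene set(s) with fewer than ", min_overlap, " overlapping genes")
  sets <- sets[keep]
  if (!length(sets)) stop("no gene set with sufficient overlap")
  n <- ncol(expr)
  out <- matrix(NA_real_, nrow(expr), length(sets),
                dimnames = list(rownames(expr), names(sets)))
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, ]
    r <- rank(x, ties.method = "average")
    ord <- order(x, decreasing = TRUE)
    w <- r[ord]^alpha
    for (j in seq_along(sets)) {
      inset <- ord %in% sets[[j]]
      win <- w * inset
      p_in <- cumsum(win) / sum(win)
      p_out <- cumsum(!inset) / (n - sum(inset))
      out[i, j] <- sum(p_in - p_out)
    }
  }
  out
}

#' ssGSEA similarity of predicted subtypes between two cohorts
#'
#' Computes per-sample enrichment scores in both cohorts over the shared gene
#' sets, averages them per predicted subtype, takes the cosine similarity of
#' the two cohorts' mean-score vectors per subtype, and returns the average
#' over subtypes. A subtype absent from either cohort is skipped with a
#' warning; if no subtype is shared, the result is `NA`.
#'
#' @param source,target `srps_cohort`s (expression is used as enrichment
#'   input, ideally quantile-normalized).
#' @param pred_source,pred_target Predicted subtype per sample in each cohort.
#' @param gene_sets Named list of gene sets.
#' @param ... Passed to [ssgsea_scores()].
#' @return Mean cosine similarity in `[-1, 1]`.
#' @export
ssgsea_similarity <- function(source, target, pred_source, pred_target,
                              gene_sets, ...) {
  es_s <- ssgsea_scores(source$expr, gene_sets, ...)
  es_t <- ssgsea_scores(target$expr, gene_sets, ...)
  subtypes <- sort(union(unique(pred_source), unique(pred_target)))
  sims <- c()
  for (s in subtypes) {
    in_s <- pred_source == s
    in_t <- pred_target == s
    if (!any(in_s) || !any(in_t)) {
      warning("subtype ", s, " absent from one cohort; skipped")
      next
    }
    v1 <- colMeans(es_s[in_s, , drop = FALSE])
    v2 <- colMeans(es_t[in_t, , drop = FALSE])
    sims <- c(sims, sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))
  }
  if (!length(sims)) return(NA_real_)
  mean(sims)
}
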