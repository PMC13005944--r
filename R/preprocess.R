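#' Joint preprocessing of a source/target cohort pair
#'
#' Applies the proteomic preprocessing pipeline to both cohorts and aligns
#' their feature spaces so a single weight matrix can act on either. Steps, in
#' order:
#'
#' 1. quantile normalization across samples (each sample's value distribution
#'    is mapped onto the common reference distribution);
#' 2. per cohort, drop proteins detected (non-missing) in fewer than
#'    `min_detect` of the samples;
#' 3. impute the remaining missing values as zero;
#' 4. z-score each protein column (population SD; all-constant columns become
#'    all-zero rather than being dropped, so signature alignment survives);
#' 5. keep only proteins present in both cohorts;
#' 6. when a signature list is supplied, intersect with it.
#'
#' The two returned cohorts carry identical, identically ordered protein ids.
#'
#' @param source,target `srps_cohort` objects with raw expression.
#' @param signature Optional character vector of protein ids (step 6).
#' @param min_detect Detection fraction threshold for step 2 (default 0.3).
#' @return List with elements `source` and `target`, both `preprocessed`.
#' @export
preprocess_pair <- function(source, target, signature = NULL, min_detect = 0.3) {
  pre_one <- function(co) {
    x <- quantile_normalize(co$expr)
    detected <- colMeans(!is.na(x)) >= min_detect
    x <- x[, detected, drop = FALSE]
    if (!ncol(x)) stop("detection filter removed every protein")
    x[is.na(x)] <- 0
    zscore_columns(x)
  }
  xs <- pre_one(source)
  xt <- pre_one(target)
  shared <- intersect(colnames(xs), colnames(xt))
  if (!length(shared)) stop("no protein shared between cohorts after filtering")
  if (!is.null(signature)) {
    shared <- intersect(shared, signature)
    if (!length(shared)) stop("signature intersection left no protein")
  }
  rebuild <- function(co, x) {
    out <- cohort(x[, shared, drop = FALSE], co$clinical, co$labels, preprocessed = TRUE)
    out
  }
  list(source = rebuild(source, xs), target = rebuild(target, xt))
}

#' Standardize a cohort pair by source-cohort statistics
#'
#' Z-scores every feature of both cohorts using the mean and population SD of
#' the source cohort alone, the way a scaler is fitted on training data and
#' applied unchanged to new data. Unlike per-cohort z-scoring, this preserves
#' any systematic source/target shift — which is the quantity a
#' domain-adaptation benchmark needs to keep — while putting the features on
#' a scale the optimizers handle well.
#'
#' Values are winsorized at `clip` source-SDs: badly shifted target features
#' stay shifted but cannot saturate a classifier's logits, mirroring the
#' routine outlier capping of intensity pipelines.
#'
#' @param source,target Feature-aligned `srps_cohort`s.
#' @param clip Winsorization bound in source-SD units (default 5;
#'   `Inf` disables).
#' @return List with standardized `source` and `target`.
#' @export
align_to_source <- function(source, target, clip = 5) {
  stopifnot(identical(colnames(source$expr), colnames(target$expr)))
  mu <- colMeans(source$expr)
  sd_pop <- sqrt(colMeans(sweep(source$expr, 2, mu)^2))
  sd_pop[sd_pop == 0] <- 1
  std <- function(co) {
    x <- sweep(sweep(co$expr, 2, mu), 2, sd_pop, "/")
    x <- pmin(pmax(x, -clip), clip)
    cohort(x, co$clinical, co$labels, preprocessed = TRUE)
  }
  list(source = std(source), target = std(target))
}

#' Quantile normalization across samples
#'
#' Maps every sample (row) onto the mean empirical distribution, so all rows
#' share the same sorted value vector; ties receive averaged quantiles and
#' missing values stay missing. Delegates to [limma::normalizeQuantiles()]
#' (which normalizes columns, hence the transposition).
#'
#' @param x Samples x proteins matrix, missing values allowed.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  out <- t(limma::normalizeQuantiles(t(x), ties = TRUE))
  dimnames(out) <- dimnames(x)
  out
}

#' Z-score matrix columns with the population SD
#'
#' Columns with zero SD are set to all-zero and counted in a message instead
#' of being dropped.
#'
#' @param x Numeric matrix without missing values.
#' @return Matrix with column means 0 and population SD 1 (where defined).
#' @export
zscore_columns <- function(x) {
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2, mu)^2))
  flat <- sd_pop == 0
  if (any(flat)) {
    message("zscore_columns: ", sum(flat), " constant column(s) set to zero")
    sd_pop[flat] <- 1
  }
  out <- sweep(sweep(x, 2, mu), 2, sd_pop, "/")
  out[, flat] <- 0
  out
}
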