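#' Per-protein Cox coefficients against delta weights
#'
#' Fits a univariate proportional-hazards model per protein (on its z-scored
#' expression) and pairs the coefficient with the protein's delta weight for
#' the chosen subtype; the Pearson correlation of the two quantifies how much
#' of the classifier's feature weighting tracks prognostic discrimination.
#'
#' @param cohort_ An `srps_cohort` with survival for `endpoint`.
#' @param delta A `delta_weight_table` over (a subset of) the cohort proteins.
#' @param subtype Subtype whose delta weights are used.
#' @param endpoint Clinical endpoint (default first table).
#' @return Data frame (`protein`, `cox_coef`, `delta_weight`) with attribute
#'   `r` (Pearson correlation); proteins with non-converging fits are skipped
#'   with a message.
#' @export
cox_coefficient_report <- function(cohort_, delta, subtype = 1, endpoint = NULL) {
  surv <- cohort_survival(cohort_, endpoint)
  x <- cohort_$expr[surv$sample_id, , drop = FALSE]
  proteins <- intersect(delta$proteins, colnames(x))
  if (!length(proteins)) stop("no shared protein between cohort and table")
  y <- survival::Surv(surv$time, surv$event)
  coefs <- rep(NA_real_, length(proteins))
  for (i in seq_along(proteins)) {
    v <- as.vector(scale(x[, proteins[i]]))
    if (all(!is.finite(v))) next
    fit <- tryCatch(
      survival::coxph(y ~ v),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit) && is.finite(stats::coef(fit)[1]))
      coefs[i] <- unname(stats::coef(fit)[1])
  }
  skipped <- sum(is.na(coefs))
  if (skipped) message("cox_coefficient_report: skipped ", skipped, " protein(s)")
  dw <- delta$delta[subtype, match(proteins, delta$proteins)]
  out <- data.frame(protein = proteins, cox_coef = coefs, delta_weight = dw)
  ok <- stats::complete.cases(out[, c("cox_coef", "delta_weight")])
  attr(out, "r") <- if (sum(ok) >= 3)
    stats::cor(out$cox_coef[ok], out$delta_weight[ok]) else NA_real_
  out
}

#' Optimal expression split for survival discrimination
#'
#' Grid search over the observed expression values of one protein for the
#' high/low threshold maximizing the log-rank score, excluding splits that
#' leave less than `min_frac` of the samples on either side.
#'
#' @param expression One protein's expression values.
#' @param times,events Survival data.
#' @param min_frac Minimum group fraction per side (default 0.1).
#' @return List with `threshold` and `score` (the maximal log-rank score).
#' @export
optimal_split_survival <- function(expression, times, events, min_frac = 0.1) {
  if (length(unique(expression)) < 2) stop("degenerate expression vector")
  n <- length(expression)
  cand <- sort(unique(expression))
  cand <- cand[-length(cand)]  # 'high' group is expression > threshold
  sizes <- vapply(cand, function(thr) sum(expression > thr), numeric(1))
  ok <- sizes >= min_frac * n & (n - sizes) >= min_frac * n
  if (!any(ok)) stop("no threshold leaves at least ", min_frac, " on both sides")
  cand <- cand[ok]
  scores <- vapply(cand, function(thr)
    logrank_score(expression > thr, times, events), numeric(1))
  best <- which.max(scores)
  list(threshold = cand[best], score = scores[best])
}
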