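#' Kaplan-Meier product-limit curve
#'
#' Estimates the survival function by the product-limit rule
#' `s_{t+1} = s_t * (1 - d_t / n_t)`, where `d_t` is the number of deaths at
#' event time `t` and `n_t` the number still at risk. Censored subjects leave
#' the risk set after their censoring time and never count as deaths.
#'
#' @param times Non-negative survival times (months).
#' @param events 0/1 event indicators (1 = event observed).
#' @return Object of class `km_curve`: `times` (distinct event times), `surv`
#'   (probability just after each event time), `at_risk`, `deaths`. The curve
#'   starts implicitly at survival 1 at time 0.
#' @export
km_curve <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  stopifnot(length(times) == length(events))
  if (any(times < 0)) stop("negative survival time")
  ut <- sort(unique(times[events == 1]))
  if (!length(ut)) {
    out <- list(times = numeric(0), surv = numeric(0),
                at_risk = numeric(0), deaths = numeric(0))
    return(structure(out, class = "km_curve"))
  }
  at_risk <- vapply(ut, function(u) sum(times >= u), numeric(1))
  deaths <- vapply(ut, function(u) sum(times == u & events == 1), numeric(1))
  surv <- cumprod(1 - deaths / at_risk)
  structure(list(times = ut, surv = surv, at_risk = at_risk, deaths = deaths),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: %d event times, final survival %.3f\n",
              length(x$times), if (length(x$surv)) min(x$surv) else 1))
  invisible(x)
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier step function on `[0, t_restrict]`; the curve
#' is carried forward flat beyond its last observed event time. Computed as an
#' exact rectangle sum over the event-time grid, no quadrature.
#'
#' @param curve A [km_curve()].
#' @param t_restrict Restriction horizon in months (default 60).
#' @return RMST in months, in `[0, t_restrict]`.
#' @export
rmst <- function(curve, t_restrict = 60) {
  stopifnot(inherits(curve, "km_curve"), t_restrict > 0)
  tt <- c(0, curve$times)
  ss <- c(1, curve$surv)
  keep <- tt < t_restrict
  tt <- tt[keep]
  ss <- ss[keep]
  widths <- diff(c(tt, t_restrict))
  sum(ss * widths)
}

#' Minimum pairwise RMST-gap reward
#'
#' Given per-subtype RMST values `tau` ordered so that subtype 1 is the
#' best-prognosis class by convention, returns
#' `min over a < b of tau[a] - tau[b]`. The reward is positive iff every
#' better-labeled subtype outlives every worse-labeled one in restricted mean.
#'
#' @param tau Numeric vector of k >= 2 RMST values, indexed by subtype.
#' @return The minimum pairwise gap (months), possibly negative.
#' @export
rmst_gap_reward <- function(tau) {
  k <- length(tau)
  if (k < 2) stop("need at least 2 subtypes")
  d <- outer(tau, tau, "-")
  min(d[upper.tri(d)])
}

#' Log-rank score
#'
#' k-group log-rank test (chi-square approximation with k-1 degrees of
#' freedom, via [survival::survdiff()]), reported as `-log10(P)`. 1.3
#' corresponds to P = 0.05.
#'
#' @param groups Subtype per sample (any atomic vector).
#' @param times,events Survival data aligned to `groups`.
#' @return Non-negative score.
#' @export
logrank_score <- function(groups, times, events) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("log-rank test needs at least 2 nonempty groups")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  p <- stats::pchisq(sd_$chisq, df = nlevels(groups) - 1, lower.tail = FALSE)
  -log10(max(p, .Machine$double.xmin))
}

#' Harrell concordance index
#'
#' Fraction of comparable subject pairs whose ordering by `score` matches the
#' ordering of their survival times, censoring-aware. `score` follows the
#' higher-is-better-prognosis convention (e.g. `p(1) - p(k)` for subtype
#' probabilities), so a perfect scorer on uncensored data yields 1. Ties in
#' time (both events) or in score count 0.5.
#'
#' @param score Per-sample prognostic score, higher = longer expected survival.
#' @param times,events Survival data.
#' @return C-index in `[0, 1]`.
#' @export
concordance_index <- function(score, times, events) {
  n <- length(score)
  stopifnot(length(times) == n, length(events) == n)
  ev <- events == 1
  # pair (i, j) with t_i < t_j and event at i: concordant when score_i < score_j
  earlier <- outer(times, times, "<") & matrix(ev, n, n)
  conc <- sum(earlier & outer(score, score, "<"))
  tied <- sum(earlier & outer(score, score, "=="))
  den <- sum(earlier)
  # equal event times, both events: comparable once, inherently half-concordant
  eq <- outer(times, times, "==") & matrix(ev, n, n) & matrix(ev, n, n, byrow = TRUE)
  eq <- eq & upper.tri(eq)
  num <- conc + 0.5 * tied + 0.5 * sum(eq)
  den <- den + sum(eq)
  if (den == 0) stop("no comparable pairs")
  num / den
}
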