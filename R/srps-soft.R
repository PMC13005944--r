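#' Probability-weighted Kaplan-Meier curve
#'
#' Soft relaxation of [km_curve()] in which each subject contributes its
#' membership weight to the death counts `d_t` and risk counts `n_t` instead
#' of a hard 0/1 count. With all weights 1 it reproduces the hard curve
#' exactly.
#'
#' @param times,events Survival data.
#' @param weights Non-negative per-subject membership weights.
#' @return A `km_curve` object on the grid of distinct hard event times.
#' @export
soft_km_curve <- function(times, events, weights) {
  stopifnot(length(weights) == length(times), all(weights >= 0))
  ut <- sort(unique(times[events == 1]))
  if (!length(ut))
    return(structure(list(times = numeric(0), surv = numeric(0),
                          at_risk = numeric(0), deaths = numeric(0)),
                     class = "km_curve"))
  at_risk <- vapply(ut, function(u) sum(weights[times >= u]), numeric(1))
  deaths <- vapply(ut, function(u) sum(weights[times == u & events == 1]), numeric(1))
  at_risk <- pmax(at_risk, 1e-12)
  surv <- cumprod(pmax(1 - deaths / at_risk, 0))
  structure(list(times = ut, surv = surv, at_risk = at_risk, deaths = deaths),
            class = "km_curve")
}

# Soft RMST of one subtype plus its analytic gradient w.r.t. the weights.
# tau = sum_j S_j * width_j with S_j = prod_{l<=j} f_l, f_l = 1 - d_l/n_l;
# d log f_l / d w_i = (A_il - D_il)/(n_l - d_l) - A_il/n_l with
# A_il = 1{t_i >= t_l}, D_il = 1{t_i = t_l, e_i = 1}, so
# d tau / d w = C %*% G, G_l = sum_{j >= l} width_j S_j.
soft_rmst_grad <- function(times, events, weights, t_restrict) {
  ut <- sort(unique(times[events == 1]))
  n <- length(times)
  if (!length(ut)) return(list(value = t_restrict, grad = rep(0, n)))
  A <- outer(times, ut, ">=") + 0
  D <- outer(times, ut, "==") * (events == 1)
  n_l <- pmax(drop(crossprod(A, weights)), 1e-12)
  d_l <- drop(crossprod(D, weights))
  f <- pmax(1 - d_l / n_l, 1e-10)
  S <- cumprod(f)
  keep <- ut < t_restrict
  widths <- rep(0, length(ut))
  if (any(keep)) widths[keep] <- diff(c(ut[keep], min(t_restrict, Inf)))
  # value: leading rectangle of height 1 plus the post-event steps
  lead <- if (any(keep)) ut[keep][1] else t_restrict
  value <- lead + sum(S * widths)
  G <- rev(cumsum(rev(S * widths)))
  denom <- n_l - d_l
  C <- sweep(A - D, 2, pmax(denom, 1e-12), "/") - sweep(A, 2, n_l, "/")
  # where the factor saturates (n_l == d_l) the clamped survival is flat zero,
  # so those columns carry no gradient
  C[, denom <= 1e-12] <- 0
  grad <- drop(C %*% G)
  list(value = value, grad = grad)
}

#' Soft RMST-gap objective
#'
#' Differentiable version of the minimum pairwise RMST gap: per-subtype
#' Kaplan-Meier curves accumulate membership probabilities rather than hard
#' counts, and the gap of the currently minimal pair is returned together with
#' its gradient with respect to the probability matrix.
#'
#' @param p n x k membership probability matrix.
#' @param times,events Survival data aligned to the rows of `p`.
#' @param t_restrict RMST horizon (months).
#' @return List with `value` (the soft gap), `tau` (per-subtype soft RMST) and
#'   `grad` (n x k gradient of `value` w.r.t. `p`).
#' @export
soft_delta_rmst <- function(p, times, events, t_restrict = 60) {
  k <- ncol(p)
  per <- lapply(seq_len(k), function(s)
    soft_rmst_grad(times, events, p[, s], t_restrict))
  tau <- vapply(per, `[[`, numeric(1), "value")
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  gaps <- tau[pairs[, 1]] - tau[pairs[, 2]]
  j <- which.min(gaps)
  a <- pairs[j, 1]; b <- pairs[j, 2]
  grad <- matrix(0, nrow(p), k)
  grad[, a] <- per[[a]]$grad
  grad[, b] <- -per[[b]]$grad
  list(value = gaps[j], tau = tau, grad = grad)
}

#' Train the soft-relaxation ablation of SRPS
#'
#' Replaces subtype sampling and the REINFORCE loss with a directly
#' differentiable objective: the classifier minimizes
#' `omega1 * l_CE - omega2 * softDeltaRMST + l1 * ||theta||_1`, where the soft
#' RMST gap weighs each subject's contribution to the per-subtype
#' Kaplan-Meier counts by its membership probability. No sampling, no reward
#' baseline.
#'
#' @inheritParams srps_train
#' @return List with `model` and `log` as in [srps_train()] (`l_re` holds
#'   `-softDeltaRMST`, `reward` the soft gap).
#' @export
srps_train_soft <- function(source, target, cfg, validation = NULL, endpoint = NULL) {
  stopifnot(inherits(cfg, "srps_config"))
  if (is.null(source$labels)) stop("source cohort must be labeled")
  xs <- source$expr; xt <- target$expr
  if (!identical(colnames(xs), colnames(xt)))
    stop("source and target must share an identically ordered feature space")
  k <- cfg$k
  ys <- one_hot(source$labels, k)
  surv <- cohort_survival(target, endpoint)
  val_surv <- if (!is.null(validation)) cohort_survival(validation, endpoint)

  set.seed(cfg$seed)
  theta <- matrix(0, k, cfg$d, dimnames = list(NULL, colnames(xs)))
  opt <- adam_init(list(theta = theta))
  n_ep <- cfg$episodes
  log_df <- data.frame(loss = numeric(n_ep), l_ce = numeric(n_ep),
                       l_re = numeric(n_ep), l_bl = 0,
                       reward = numeric(n_ep), val_drmst = rep(NA_real_, n_ep))
  best <- list(episode = NA_integer_, val = -Inf, theta = theta)

  for (ep in seq_len(n_ep)) {
    xs_d <- xs
    if (cfg$dropout_su > 0) xs_d <- xs * dropout_mask(nrow(xs), cfg$d, cfg$dropout_su)
    ps <- softmax_rows(xs_d %*% t(theta))
    l_ce <- supervised_loss(ps, ys)
    g_ce <- t(ps - ys) %*% xs_d / nrow(xs)

    xt_d <- xt
    if (cfg$dropout_rl > 0) xt_d <- xt * dropout_mask(nrow(xt), cfg$d, cfg$dropout_rl)
    pt <- softmax_rows(xt_d %*% t(theta))
    soft <- soft_delta_rmst(pt, surv$time, surv$event, cfg$t_restrict)
    # chain -value through the softmax rows: dL/dlogit = p * (g - sum(g * p))
    gp <- -soft$grad
    dlogit <- pt * (gp - rowSums(gp * pt))
    g_soft <- t(dlogit) %*% xt_d

    loss <- cfg$omega1 * l_ce - cfg$omega2 * soft$value + cfg$l1_coeff * sum(abs(theta))
    if (!is.finite(loss)) stop("non-finite loss at episode ", ep)
    grad <- cfg$omega1 * g_ce + cfg$omega2 * g_soft + cfg$l1_coeff * sign(theta)
    stp <- adam_step(opt, list(theta = theta), list(theta = grad), cfg$lr_cls)
    opt <- stp$state
    theta <- stp$params$theta

    val <- NA_real_
    if (!is.null(validation)) {
      cls_val <- max.col(validation$expr %*% t(theta), ties.method = "first")
      val <- episode_reward(cls_val, val_surv$time, val_surv$event, k, cfg$t_restrict)
      if (val > best$val) best <- list(episode = ep, val = val, theta = theta)
    }
    log_df[ep, ] <- c(loss, l_ce, -soft$value, 0, soft$value, val)
  }
  if (cfg$early_stop && !is.null(validation) && is.finite(best$val)) {
    theta <- best$theta
    attr(log_df, "best_episode") <- best$episode
  } else attr(log_df, "best_episode") <- n_ep
  list(model = new_srps_model(theta, NULL, 0, cfg), log = log_df)
}
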