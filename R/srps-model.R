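#' SRPS training configuration
#'
#' Collects every tunable of the survival-reinforced classifier. Defaults
#' follow the published training settings: full-batch training for `episodes`
#' iterations with Adam, a bias-free linear softmax classifier with L1
#' regularization and input dropout, and a 2-hidden-layer sigmoid perceptron
#' as reward baseline.
#'
#' @param k Number of subtypes (smaller index = better prognosis).
#' @param d Feature dimension.
#' @param omega1 Weight of the supervised cross-entropy loss, in `[0, 1]`.
#' @param omega2 Weight of the REINFORCE loss, in `[0, 1]` (default 1).
#' @param l1_coeff L1 penalty coefficient on the classifier weights.
#' @param dropout_su Input dropout rate for the supervised pass.
#' @param dropout_rl Input dropout rate for the reinforcement pass.
#' @param n_hidden Hidden width of the baseline perceptron.
#' @param lr_cls,lr_bl Adam learning rates for the classifier and the baseline.
#' @param episodes Full-batch training iterations (default 10000; reduce for
#'   quick experiments).
#' @param early_stop When `TRUE`, return the snapshot with the highest
#'   validation RMST gap instead of the final model.
#' @param t_restrict RMST horizon in months (default 60).
#' @param use_baseline When `FALSE`, the learned baseline is ablated and the
#'   advantage is the raw reward (`q = r`).
#' @param seed Integer seed making a training run exactly reproducible.
#' @return List of class `srps_config`.
#' @export
srps_config <- function(k, d, omega1 = 0.1, omega2 = 1, l1_coeff = 1e-5,
                        dropout_su = 0, dropout_rl = 0, n_hidden = 10,
                        lr_cls = 0.01, lr_bl = 0.01, episodes = 10000,
                        early_stop = FALSE, t_restrict = 60,
                        use_baseline = TRUE, seed = 0) {
  stopifnot(k >= 2, d >= 1, omega1 >= 0, omega1 <= 1, omega2 >= 0, omega2 <= 1,
            dropout_su >= 0, dropout_su < 1, dropout_rl >= 0, dropout_rl < 1,
            episodes > 0, t_restrict > 0)
  structure(list(k = as.integer(k), d = as.integer(d), omega1 = omega1,
                 omega2 = omega2, l1_coeff = l1_coeff, dropout_su = dropout_su,
                 dropout_rl = dropout_rl, n_hidden = as.integer(n_hidden),
                 lr_cls = lr_cls, lr_bl = lr_bl, episodes = as.integer(episodes),
                 early_stop = isTRUE(early_stop), t_restrict = t_restrict,
                 use_baseline = isTRUE(use_baseline), seed = as.integer(seed)),
            class = "srps_config")
}

new_srps_model <- function(theta, baseline, b_c, config) {
  stopifnot(is.matrix(theta), all(is.finite(theta)))
  structure(list(theta = theta, baseline = baseline, b_c = b_c, config = config),
            class = "srps_model")
}

#' @export
print.srps_model <- function(x, ...) {
  cat(sprintf("srps_model: linear softmax classifier, %d subtypes x %d features\n",
              nrow(x$theta), ncol(x$theta)))
  invisible(x)
}

#' Subtype probabilities under the linear softmax classifier
#'
#' Logits are `theta %*% x` (no bias); probabilities are the row-wise softmax.
#' Input dropout is applied only when `training = TRUE`, using inverted
#' scaling so inference needs none.
#'
#' @param model An `srps_model`.
#' @param x Feature matrix, samples x d.
#' @param dropout Input dropout rate used when training.
#' @param training Logical; sampling-phase forward pass.
#' @return n x k matrix with rows summing to 1.
#' @export
predict_proba <- function(model, x, dropout = 0, training = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$theta))
    stop("feature dimension mismatch: model expects ", ncol(model$theta),
         ", got ", ncol(x))
  if (training && dropout > 0) {
    mask <- dropout_mask(nrow(x), ncol(x), dropout)
    x <- x * mask
  }
  softmax_rows(x %*% t(model$theta))
}

#' Deterministic subtype prediction
#'
#' Argmax of the predicted probabilities; exact ties resolve to the smaller
#' subtype index (the better-prognosis class).
#'
#' @param model An `srps_model`.
#' @param x Feature matrix.
#' @return Integer vector of subtypes in `1..k`.
#' @export
predict_subtype <- function(model, x) {
  p <- predict_proba(model, x)
  max.col(p, ties.method = "first")
}

#' @param object An `srps_model`.
#' @param newdata Feature matrix.
#' @param type `"class"` for subtypes, `"prob"` for the probability matrix.
#' @param ... Unused.
#' @rdname predict_subtype
#' @export
predict.srps_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (type == "prob") predict_proba(object, newdata) else predict_subtype(object, newdata)
}

#' Sample subtype assignments from predicted probabilities
#'
#' One categorical draw per sample, used only during training to explore
#' alternative stratifications.
#'
#' @param p n x k probability matrix; rows must sum to 1 within 1e-6.
#' @return n x k one-hot matrix.
#' @export
sample_subtypes <- function(p) {
  if (any(abs(rowSums(p) - 1) > 1e-6)) stop("probability rows must sum to 1")
  cs <- t(apply(p, 1, cumsum))
  u <- stats::runif(nrow(p))
  idx <- rowSums(cs < u) + 1L
  idx <- pmin(idx, ncol(p))
  one_hot(idx, ncol(p))
}

#' Supervised cross-entropy loss
#'
#' Mean over labeled samples of `-sum_s y(s) log p(s)`; probabilities are
#' clipped at 1e-12 before the log.
#'
#' @param p n x k probability matrix.
#' @param y n x k one-hot label matrix.
#' @return Non-negative scalar.
#' @export
supervised_loss <- function(p, y) {
  stopifnot(all(dim(p) == dim(y)))
  mean(-rowSums(y * log(clip_prob(p))))
}

#' Episode reward: minimum pairwise RMST gap of the sampled stratification
#'
#' Computes the per-subtype RMST of the sampled assignment on the target
#' cohort's survival data and returns [rmst_gap_reward()]. If any subtype
#' received no sample, the reward is `-t_restrict`: a collapse penalty that
#' deters the degenerate all-one-subtype policy (the RMST of an empty group is
#' undefined).
#'
#' @param y_hat n x k one-hot sampled assignment, or an integer subtype vector.
#' @param times,events Target-cohort survival data aligned to the rows.
#' @param k Number of subtypes.
#' @param t_restrict RMST horizon (months).
#' @return Scalar reward in months.
#' @export
episode_reward <- function(y_hat, times, events, k, t_restrict = 60) {
  cls <- if (is.matrix(y_hat)) max.col(y_hat, ties.method = "first") else as.integer(y_hat)
  tau <- numeric(k)
  for (s in seq_len(k)) {
    in_s <- cls == s
    if (!any(in_s)) return(-t_restrict)
    tau[s] <- rmst(km_curve(times[in_s], events[in_s]), t_restrict)
  }
  rmst_gap_reward(tau)
}

#' Advantage of an episode under the learned baseline
#'
#' `q_i = r - b_i - b_c`, treated as a constant in the policy-gradient loss
#' (no gradient flows through it into the classifier).
#'
#' @param r Scalar episode reward.
#' @param b_i Per-sample baseline predictions.
#' @param b_c Scalar baseline constant.
#' @return Per-sample advantage vector.
#' @export
advantage <- function(r, b_i, b_c) r - b_i - b_c

#' Baseline regression loss
#'
#' L2 norm of the residual vector `r - b_i - b_c`.
#'
#' @inheritParams advantage
#' @return Non-negative scalar.
#' @export
baseline_loss <- function(r, b_i, b_c) sqrt(sum((r - b_i - b_c)^2))

#' REINFORCE policy-gradient loss
#'
#' Mean over samples of `-q_i * log p_i(y_hat_i)`. Minimizing it with `q`
#' held constant follows the sampled policy gradient of the expected reward.
#'
#' @param p n x k probability matrix.
#' @param y_hat n x k one-hot sampled assignment.
#' @param q Per-sample advantage (constant w.r.t. the classifier).
#' @return Scalar loss.
#' @export
reinforce_loss <- function(p, y_hat, q) {
  stopifnot(all(dim(p) == dim(y_hat)), length(q) == nrow(p))
  mean(-q * log(clip_prob(rowSums(p * y_hat))))
}
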