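#' Train the survival-reinforced classifier
#'
#' Full-batch training of the linear softmax classifier with the combined loss
#' `omega1 * l_CE + omega2 * l_RE + l1_coeff * ||theta||_1`. Each episode:
#'
#' 1. forward the labeled source batch with dropout `dropout_su` and compute
#'    the supervised cross-entropy;
#' 2. forward the unlabeled target batch with dropout `dropout_rl`, sample one
#'    subtype per patient, score the sampled stratification by its minimum
#'    pairwise RMST gap, and form per-sample advantages
#'    `q_i = r - b_i - b_c` from the learned baseline;
#' 3. take one Adam step on the classifier;
#' 4. take one Adam step on the baseline parameters (including the scalar
#'    `b_c`) minimizing the residual L2 norm — a separate optimizer, so
#'    baseline error never leaks into the classifier.
#'
#' With `early_stop`, the returned model is the episode snapshot with the
#' highest validation RMST gap, where the validation gap is the episode reward
#' of the deterministic (argmax) predictions on the validation cohort.
#'
#' @param source Labeled `srps_cohort` (the subtype definitions to transfer).
#' @param target `srps_cohort` with survival data for `endpoint` (labels, if
#'   any, are never read).
#' @param cfg An [srps_config()]; its `seed` makes the run reproducible.
#' @param validation Optional `srps_cohort` with survival, used for the
#'   early-stopping snapshot rule.
#' @param endpoint Endpoint of the target clinical table driving the reward.
#' @return List with `model` (an `srps_model`) and `log` (a data frame with
#'   per-episode `loss`, `l_ce`, `l_re`, `l_bl`, `reward`, `val_drmst`, plus
#'   attribute `best_episode`).
#' @export
srps_train <- function(source, target, cfg, validation = NULL, endpoint = NULL) {
  stopifnot(inherits(cfg, "srps_config"))
  if (is.null(source$labels)) stop("source cohort must be labeled")
  xs <- source$expr
  xt <- target$expr
  if (ncol(xs) != ncol(xt) || !identical(colnames(xs), colnames(xt)))
    stop("source and target must share an identically ordered feature space")
  if (ncol(xs) != cfg$d) stop("cfg$d does not match the feature dimension")
  k <- cfg$k
  ys <- one_hot(source$labels, k)
  surv <- cohort_survival(target, endpoint)
  if (length(surv$time) != nrow(xt))
    stop("target survival must cover every target sample")
  val_surv <- if (!is.null(validation)) cohort_survival(validation, endpoint)

  set.seed(cfg$seed)
  theta <- matrix(0, k, cfg$d, dimnames = list(NULL, colnames(xs)))
  use_rl <- cfg$omega2 > 0
  bl <- if (use_rl && cfg$use_baseline) baseline_init(cfg$d, cfg$n_hidden)
  b_c <- 0
  opt_cls <- adam_init(list(theta = theta))
  opt_bl <- if (!is.null(bl)) adam_init(c(bl, list(b_c = b_c)))

  n_ep <- cfg$episodes
  log_df <- data.frame(loss = numeric(n_ep), l_ce = numeric(n_ep),
                       l_re = numeric(n_ep), l_bl = numeric(n_ep),
                       reward = numeric(n_ep), val_drmst = rep(NA_real_, n_ep))
  best <- list(episode = NA_integer_, val = -Inf, theta = theta)
  n_collapsed <- 0L

  for (ep in seq_len(n_ep)) {
    model_ep <- new_srps_model(theta, bl, b_c, cfg)

    # supervised pass
    xs_d <- xs
    if (cfg$dropout_su > 0) xs_d <- xs * dropout_mask(nrow(xs), cfg$d, cfg$dropout_su)
    ps <- softmax_rows(xs_d %*% t(theta))
    l_ce <- supervised_loss(ps, ys)
    g_ce <- t(ps - ys) %*% xs_d / nrow(xs)

    # reinforcement pass
    l_re <- 0; r <- NA_real_; l_bl <- 0
    g_re <- 0
    if (use_rl) {
      xt_d <- xt
      if (cfg$dropout_rl > 0) xt_d <- xt * dropout_mask(nrow(xt), cfg$d, cfg$dropout_rl)
      pt <- softmax_rows(xt_d %*% t(theta))
      y_hat <- sample_subtypes(pt)
      r <- episode_reward(y_hat, surv$time, surv$event, k, cfg$t_restrict)
      if (r == -cfg$t_restrict) n_collapsed <- n_collapsed + 1L
      if (!is.null(bl)) {
        fwd <- baseline_forward(bl, xt)
        b_i <- fwd$b
      } else {
        b_i <- rep(0, nrow(xt))
      }
      q <- advantage(r, b_i, b_c)
      l_re <- reinforce_loss(pt, y_hat, q)
      g_re <- t((pt - y_hat) * q) %*% xt_d / nrow(xt)

      # baseline update (separate optimizer; classifier gradient sees q as constant)
      if (!is.null(bl)) {
        resid <- r - b_i - b_c
        l_bl <- sqrt(sum(resid^2))
        if (l_bl > 0) {
          db <- -resid / l_bl
          g_bl <- baseline_backward(bl, xt, fwd, db)
          g_bl$b_c <- sum(db)
          stp <- adam_step(opt_bl, c(bl, list(b_c = b_c)), g_bl, cfg$lr_bl)
          opt_bl <- stp$state
          bl <- stp$params[setdiff(names(stp$params), "b_c")]
          b_c <- stp$params$b_c
        }
      }
    }

    loss <- cfg$omega1 * l_ce + cfg$omega2 * l_re + cfg$l1_coeff * sum(abs(theta))
    if (!is.finite(loss))
      stop("non-finite loss at episode ", ep, " (l_ce=", l_ce, ", l_re=", l_re, ")")

    grad <- cfg$omega1 * g_ce + cfg$omega2 * g_re + cfg$l1_coeff * sign(theta)
    stp <- adam_step(opt_cls, list(theta = theta), list(theta = grad), cfg$lr_cls)
    opt_cls <- stp$state
    theta <- stp$params$theta

    val <- NA_real_
    if (!is.null(validation)) {
      cls_val <- max.col(validation$expr %*% t(theta), ties.method = "first")
      val <- episode_reward(cls_val, val_surv$time, val_surv$event, k, cfg$t_restrict)
      if (val > best$val) best <- list(episode = ep, val = val, theta = theta)
    }
    log_df[ep, ] <- c(loss, l_ce, l_re, l_bl, r, val)
  }

  if (n_collapsed > 0)
    message("srps_train: collapse penalty triggered in ", n_collapsed, " episode(s)")
  if (cfg$early_stop && !is.null(validation) && is.finite(best$val)) {
    theta <- best$theta
    attr(log_df, "best_episode") <- best$episode
  } else {
    attr(log_df, "best_episode") <- n_ep
  }
  list(model = new_srps_model(theta, bl, b_c, cfg), log = log_df)
}
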