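#' Accuracy map over the toy grid
#'
#' Evaluates one subtyping strategy on every cell of the 121-cell toy grid and
#' stores its test accuracy on the 20% target hold-out. Strategies:
#'
#' * `"feature_dnn"` — a DNN trained on the labeled source cohort only;
#' * `"survival_threshold"` — the theoretical reference that assigns subtype 1
#'   iff the patient's survival time exceeds the threshold (it reads survival,
#'   never features);
#' * `"srps"` — the survival-reinforced classifier trained on the labeled
#'   source plus the unlabeled target training split.
#'
#' @param cells Output of [make_toy_grid()].
#' @param strategy One of the three strategy names.
#' @param test_frac Target hold-out fraction (default 0.2).
#' @param episodes Training budget per cell for the learned strategies.
#' @param threshold Survival threshold in months (default 30).
#' @param seed Seed for the per-cell train/test splits.
#' @return 11 x 11 matrix, rows indexed by the batch-noise weight alpha,
#'   columns by the survival swap ratio.
#' @export
accuracy_map <- function(cells, strategy = c("feature_dnn", "survival_threshold", "srps"),
                         test_frac = 0.2, episodes = 300, threshold = 30, seed = 0) {
  strategy <- match.arg(strategy)
  alphas <- sort(unique(vapply(cells, `[[`, numeric(1), "alpha")))
  swaps <- sort(unique(vapply(cells, `[[`, numeric(1), "swap")))
  acc <- matrix(NA_real_, length(alphas), length(swaps),
                dimnames = list(alpha = alphas, swap = swaps))
  for (cell in cells) {
    # the hold-out split depends on the swap level only, matching the survival
    # draw, so survival-based accuracy is exactly constant along the alpha axis
    set.seed(seed + round(1e6 * cell$swap))
    n_t <- n_samples(cell$target)
    test_idx <- sort(sample(n_t, round(test_frac * n_t)))
    tgt_test <- cohort_subset(cell$target, test_idx)
    tgt_train <- cohort_subset(cell$target, setdiff(seq_len(n_t), test_idx))
    pred <- switch(strategy,
      survival_threshold = {
        surv <- cohort_survival(tgt_test, "OS")
        ifelse(surv$time > threshold, 1L, 2L)
      },
      feature_dnn = {
        m <- train_dnn(cell$source, dnn_config(epochs = episodes, seed = seed))
        predict(m, tgt_test$expr)
      },
      srps = {
        cfg <- srps_config(k = 2, d = ncol(cell$source$expr),
                           episodes = episodes, seed = seed)
        fit <- srps_train(cell$source, tgt_train, cfg)
        predict(fit$model, tgt_test$expr)
      })
    acc[match(cell$alpha, alphas), match(cell$swap, swaps)] <-
      accuracy(pred, tgt_test$labels)
  }
  acc
}

#' Residual accuracy map and one-sided t-test
#'
#' Element-wise difference `map_a - map_b` together with a one-sample,
#' one-sided Student t-test of whether the residuals in the chosen region are
#' above zero. The `"upper_right"` region is the block with normalized batch
#' effect >= 0.5 and survival correlation >= 0.5 (alpha >= half its maximum,
#' swap <= half its maximum).
#'
#' @param map_a,map_b Equal-shape accuracy matrices from [accuracy_map()].
#' @param region `"all"` or `"upper_right"`.
#' @return List with `residual` (matrix), `t` and `p`.
#' @export
residual_map_test <- function(map_a, map_b, region = c("all", "upper_right")) {
  region <- match.arg(region)
  stopifnot(all(dim(map_a) == dim(map_b)))
  res <- map_a - map_b
  sel <- res
  if (region == "upper_right") {
    alphas <- as.numeric(rownames(res))
    swaps <- as.numeric(colnames(res))
    sel <- res[alphas >= max(alphas) / 2, swaps <= max(swaps) / 2, drop = FALSE]
  }
  v <- as.vector(sel)
  if (stats::sd(v) < 1e-12) {
    # degenerate residuals: identical maps give t = 0, P = 0.5 by convention
    zero <- abs(mean(v)) < 1e-12
    t_stat <- if (zero) 0 else sign(mean(v)) * Inf
    p <- if (zero) 0.5 else if (mean(v) > 0) 0 else 1
  } else {
    ht <- stats::t.test(v, alternative = "greater", mu = 0)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  list(residual = res, t = t_stat, p = p)
}

#' Write an accuracy map as TSV
#'
#' @param map Matrix from [accuracy_map()].
#' @param path Output path.
#' @export
write_accuracy_map <- function(map, path) {
  df <- data.frame(alpha = rownames(map), map, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
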