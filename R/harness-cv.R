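#' Classification accuracy
#'
#' Fraction of correct predictions.
#'
#' @param pred,truth Equal-length subtype vectors.
#' @return Value in `[0, 1]`.
#' @export
accuracy <- function(pred, truth) {
  if (!length(pred)) stop("empty prediction vector")
  stopifnot(length(pred) == length(truth))
  mean(pred == truth)
}

#' Repeated k-fold cross-validation plan
#'
#' Each repeat draws its own seed, splits the samples evenly into `n_folds`
#' folds and rotates the test fold; the fold after the test fold (cyclically)
#' is the validation fold and the remaining folds train.
#'
#' @param n_folds Folds per repeat (default 5).
#' @param n_repeats Repeats (default 5).
#' @param seeds Per-repeat seeds (default `0:(n_repeats-1)`).
#' @return List of class `cv_plan`.
#' @export
cv_plan <- function(n_folds = 5, n_repeats = 5, seeds = seq_len(n_repeats) - 1L) {
  stopifnot(n_folds >= 2, length(seeds) == n_repeats)
  structure(list(n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
                 seeds = as.integer(seeds)),
            class = "cv_plan")
}

fold_assignment <- function(n, n_folds) sample(rep(seq_len(n_folds), length.out = n))

#' Hyperparameter grid for SRPS model selection
#'
#' Cartesian product of the default search options: baseline width
#' `n_hidden` in \{10, 100\}, `omega1` in \{0.1, 0.01, 0.001\}, `omega2` = 1,
#' `l1` in \{1e-5, 1e-4\}, `dropout_su` in \{0, 0.3, 0.8\}, `dropout_rl` in
#' \{0, 0.2\} and `early_stop` in \{TRUE, FALSE\} — 144 configurations.
#'
#' @param n_hidden,omega1,omega2,l1,dropout_su,dropout_rl,early_stop Option
#'   vectors; defaults are the standard search sets.
#' @return Data frame with one row per configuration.
#' @export
hyper_grid <- function(n_hidden = c(10, 100), omega1 = c(0.1, 0.01, 0.001),
                       omega2 = 1, l1 = c(1e-5, 1e-4),
                       dropout_su = c(0, 0.3, 0.8), dropout_rl = c(0, 0.2),
                       early_stop = c(TRUE, FALSE)) {
  expand.grid(n_hidden = n_hidden, omega1 = omega1, omega2 = omega2, l1 = l1,
              dropout_su = dropout_su, dropout_rl = dropout_rl,
              early_stop = early_stop, KEEP.OUT.ATTRS = FALSE)
}

#' Pluggable classifier methods for the evaluation harness
#'
#' Each method is a list with a `name` and a
#' `fit(source, target, validation, params, seed)` function returning an
#' object with a `predict(object, x, type)` method; the harness treats all
#' classifiers uniformly. `params` is one row of a hyperparameter grid (may
#' be empty), `seed` the fold-level seed.
#'
#' @param episodes,t_restrict,endpoint Training budget, RMST horizon, and
#'   reward endpoint for `srps_method()` / `soft_method()`.
#' @param ... Fixed configuration overrides passed to the underlying config
#'   constructor.
#' @return A method object.
#' @name harness_methods
NULL

grid_value <- function(params, key, default) {
  if (!is.null(params[[key]]) && !is.na(params[[key]])) params[[key]] else default
}

#' @rdname harness_methods
#' @export
srps_method <- function(episodes = 1000, t_restrict = 60, endpoint = NULL, ...) {
  fixed <- list(...)
  list(name = "SRPS", fit = function(source, target, validation, params, seed) {
    args <- list(k = max(source$labels), d = ncol(source$expr),
                 omega1 = grid_value(params, "omega1", 0.1),
                 omega2 = grid_value(params, "omega2", 1),
                 l1_coeff = grid_value(params, "l1", 1e-5),
                 dropout_su = grid_value(params, "dropout_su", 0),
                 dropout_rl = grid_value(params, "dropout_rl", 0),
                 n_hidden = grid_value(params, "n_hidden", 10),
                 early_stop = grid_value(params, "early_stop", FALSE),
                 episodes = episodes, t_restrict = t_restrict, seed = seed)
    args[names(fixed)] <- fixed
    cfg <- do.call(srps_config, args)
    srps_train(source, target, cfg, validation = validation,
               endpoint = endpoint)$model
  })
}

#' @rdname harness_methods
#' @export
soft_method <- function(episodes = 1000, t_restrict = 60, endpoint = NULL, ...) {
  fixed <- list(...)
  list(name = "SRPS(soft)", fit = function(source, target, validation, params, seed) {
    args <- list(k = max(source$labels), d = ncol(source$expr),
                 omega1 = grid_value(params, "omega1", 0.1),
                 omega2 = grid_value(params, "omega2", 1),
                 l1_coeff = grid_value(params, "l1", 1e-5),
                 episodes = episodes, t_restrict = t_restrict, seed = seed)
    args[names(fixed)] <- fixed
    cfg <- do.call(srps_config, args)
    srps_train_soft(source, target, cfg, validation = validation,
                    endpoint = endpoint)$model
  })
}

#' @rdname harness_methods
#' @export
dnn_method <- function(...) {
  fixed <- list(...)
  list(name = "DNN", fit = function(source, target, validation, params, seed) {
    args <- c(fixed[setdiff(names(fixed), "seed")], list(seed = seed))
    train_dnn(source, do.call(dnn_config, args))
  })
}

#' @rdname harness_methods
#' @export
dann_method <- function(...) {
  fixed <- list(...)
  list(name = "DANN", fit = function(source, target, validation, params, seed) {
    args <- c(fixed[setdiff(names(fixed), "seed")], list(seed = seed))
    train_dann(source, target, do.call(dann_config, args))
  })
}

eval_model <- function(model, src_test, tgt_test, k, gene_sets = NULL) {
  out <- list()
  out$acc_source <- accuracy(predict(model, src_test$expr), src_test$labels)
  pt <- predict(model, tgt_test$expr, type = "prob")
  cls_t <- max.col(pt, ties.method = "first")
  out$acc_target <- if (!is.null(tgt_test$labels))
    accuracy(cls_t, tgt_test$labels) else NA_real_
  for (ep in names(tgt_test$clinical)) {
    surv <- cohort_survival(tgt_test, ep)
    out[[paste0("logrank_", ep)]] <- tryCatch(
      logrank_score(cls_t, surv$time, surv$event), error = function(e) NA_real_)
    out[[paste0("cindex_", ep)]] <- tryCatch(
      concordance_index(pt[, 1] - pt[, k], surv$time, surv$event),
      error = function(e) NA_real_)
  }
  if (!is.null(gene_sets)) {
    out$ssgsea <- tryCatch(
      ssgsea_similarity(src_test, tgt_test,
                        predict(model, src_test$expr), cls_t, gene_sets),
      error = function(e) NA_real_)
  }
  out
}

select_model <- function(models, src_val, tgt_val, selection, gene_sets, k) {
  scores <- vapply(models, function(m) {
    if (selection == "val_accuracy") {
      accuracy(predict(m, src_val$expr), src_val$labels)
    } else {
      surv <- cohort_survival(tgt_val, "OS")
      cls <- predict(m, tgt_val$expr)
      lr <- tryCatch(logrank_score(cls, surv$time, surv$event),
                     error = function(e) -Inf)
      sim <- ssgsea_similarity(src_val, tgt_val, predict(m, src_val$expr),
                               cls, gene_sets)
      if (is.na(sim) || sim < 0.5) -Inf else lr
    }
  }, numeric(1))
  if (all(!is.finite(scores))) scores <- rep(0, length(models))
  which.max(scores)
}

#' Cross-validated evaluation of a classifier method
#'
#' Runs the repeated k-fold protocol: per repeat the source and target
#' cohorts are each split evenly into folds; per rotation, three folds train,
#' one validates (model selection over `grid` by the chosen rule) and one
#' tests. Reported per test fold: source accuracy, target accuracy (when
#' target labels exist, i.e. simulated data), log-rank score and concordance
#' index per target endpoint (C-index score is `p(1) - p(k)`), and optionally
#' ssGSEA similarity.
#'
#' @param source,target Preprocessed, feature-aligned `srps_cohort`s.
#' @param method A method object (see [srps_method()]).
#' @param plan A [cv_plan()].
#' @param grid Optional hyperparameter data frame (one model is fit per row
#'   per fold); `NULL` fits a single default configuration.
#' @param selection `"val_accuracy"` (labeled validation accuracy on the
#'   source fold) or `"logrank_ssgsea"` (highest validation log-rank score for
#'   OS among models with ssGSEA similarity >= 0.5; requires `gene_sets`).
#' @param gene_sets Optional named list of gene sets.
#' @return Object of class `srps_eval_report`: `folds` data frame and
#'   `summary` (mean and SD per metric over all repeats x folds).
#' @export
run_cv <- function(source, target, method, plan = cv_plan(),
                   grid = NULL, selection = c("val_accuracy", "logrank_ssgsea"),
                   gene_sets = NULL) {
  selection <- match.arg(selection)
  if (selection == "logrank_ssgsea" && is.null(gene_sets))
    stop("selection = 'logrank_ssgsea' requires gene_sets")
  k <- max(source$labels)
  rows <- list()
  for (rep_i in seq_len(plan$n_repeats)) {
    set.seed(plan$seeds[rep_i])
    f_src <- fold_assignment(n_samples(source), plan$n_folds)
    f_tgt <- fold_assignment(n_samples(target), plan$n_folds)
    for (fold in seq_len(plan$n_folds)) {
      val_fold <- fold %% plan$n_folds + 1L
      part <- function(co, f, which) {
        idx <- switch(which, test = f == fold, val = f == val_fold,
                      train = f != fold & f != val_fold)
        cohort_subset(co, which(idx))
      }
      src_tr <- part(source, f_src, "train"); src_va <- part(source, f_src, "val")
      src_te <- part(source, f_src, "test")
      tgt_tr <- part(target, f_tgt, "train"); tgt_va <- part(target, f_tgt, "val")
      tgt_te <- part(target, f_tgt, "test")
      fit_seed <- plan$seeds[rep_i] * 1000L + fold
      configs <- if (is.null(grid)) list(list())
        else lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
      models <- lapply(configs, function(cfg)
        method$fit(src_tr, tgt_tr, tgt_va, cfg, fit_seed))
      best <- if (length(models) == 1) 1L
        else select_model(models, src_va, tgt_va, selection, gene_sets, k)
      met <- eval_model(models[[best]], src_te, tgt_te, k, gene_sets)
      rows[[length(rows) + 1L]] <-
        c(list(method = method$name, rep = rep_i, fold = fold, config = best), met)
    }
  }
  folds <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  metric_cols <- setdiff(names(folds), c("method", "rep", "fold", "config"))
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(folds[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(folds[[m]], na.rm = TRUE), numeric(1)),
    row.names = NULL)
  structure(list(method = method$name, folds = folds, summary = summary,
                 plan = plan),
            class = "srps_eval_report")
}

#' @export
print.srps_eval_report <- function(x, ...) {
  cat("srps_eval_report:", x$method, "-",
      x$plan$n_repeats, "x", x$plan$n_folds, "fold CV\n")
  print(x$summary, digits = 3)
  invisible(x)
}
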