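constant_method <- function(class = 1L) {
  list(name = "constant", fit = function(source, target, validation, params, seed) {
    structure(list(k = max(source$labels), class = class), class = "const_model")
  })
}

predict.const_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  n <- nrow(newdata)
  if (type == "class") return(rep(object$class, n))
  p <- matrix(0, n, object$k)
  p[, object$class] <- 1
  p
}
registerS3method("predict", "const_model", predict.const_model)

test_that("accuracy is the fraction of correct predictions", {
  expect_equal(accuracy(c(1, 1, 2, 2, 1, 2, 1, 1, 2, 2),
                        c(1, 1, 2, 2, 1, 2, 2, 2, 2, 2)), 0.8)
  expect_equal(accuracy(1:5, 1:5), 1)
  truth <- sample(rep(1:3, times = c(5, 3, 2)))
  expect_equal(accuracy(rep(2, 10), truth), 0.3)
  expect_error(accuracy(integer(0), integer(0)), "empty")
})

test_that("the default hyperparameter grid enumerates 144 configurations", {
  g <- hyper_grid()
  expect_equal(nrow(g), 144L)
  expect_equal(nrow(unique(g)), 144L)
  expect_setequal(unique(g$omega1), c(0.1, 0.01, 0.001))
  expect_setequal(unique(g$n_hidden), c(10, 100))
  expect_equal(unique(g$omega2), 1)
})

test_that("cross-validation rotates every sample through the test fold once", {
  plan <- cv_plan(n_folds = 5, n_repeats = 2, seeds = c(3, 4))
  set.seed(plan$seeds[1])
  f <- srps:::fold_assignment(47, 5)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(max(table(f)) - min(table(f)) <= 1)
  # each fold is the test fold exactly once per repeat by construction
  expect_equal(length(unique(f)), plan$n_folds)
})

test_that("run_cv with a constant classifier reports the majority-class frequency", {
  pair <- make_toy_pair(toy_grid_spec(n_per_cohort = 60, seed = 5), alpha = 0, swap = 0)
  plan <- cv_plan(n_folds = 3, n_repeats = 2, seeds = c(0, 1))
  rep_ <- run_cv(pair$source, pair$target, constant_method(1L), plan)
  expect_s3_class(rep_, "srps_eval_report")
  expect_equal(nrow(rep_$folds), 6L)
  # balanced subtypes: a constant predictor scores the class frequency
  expect_equal(mean(rep_$folds$acc_target), 0.5, tolerance = 0.1)
  # every target sample tested once per repeat
  expect_true(all(c("acc_source", "acc_target", "logrank_OS", "cindex_OS") %in%
                    names(rep_$folds)))
  expect_error(run_cv(pair$source, pair$target, constant_method(), plan,
                      selection = "logrank_ssgsea"), "gene_sets")
})

test_that("run_cv trains and evaluates the survival-reinforced classifier", {
  pair <- make_toy_pair(toy_grid_spec(n_per_cohort = 100, seed = 6), alpha = 0, swap = 0)
  plan <- cv_plan(n_folds = 5, n_repeats = 1, seeds = 0)
  rep_ <- run_cv(pair$source, pair$target, srps_method(episodes = 150), plan)
  expect_equal(nrow(rep_$folds), 5L)
  acc <- rep_$summary$mean[rep_$summary$metric == "acc_target"]
  expect_gte(acc, 0.85)
  sds <- rep_$summary$sd[rep_$summary$metric == "acc_target"]
  expect_true(is.finite(sds))
})

test_that("grid selection picks the configuration with the best validation score", {
  pair <- make_toy_pair(toy_grid_spec(n_per_cohort = 60, seed = 7), alpha = 0, swap = 0)
  plan <- cv_plan(n_folds = 3, n_repeats = 1, seeds = 0)
  grid <- data.frame(omega1 = c(0.1, 0.1), omega2 = c(1, 1),
                     dropout_su = c(0, 0.3))
  rep_ <- run_cv(pair$source, pair$target, srps_method(episodes = 60), plan, grid = grid)
  expect_true(all(rep_$folds$config %in% 1:2))
})

test_that("residual maps and their one-sided test behave at the boundaries", {
  m <- matrix(runif(121), 11, 11,
              dimnames = list(alpha = seq(0, 4, 0.4), swap = seq(0, 0.2, 0.02)))
  same <- residual_map_test(m, m)
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)
  up <- residual_map_test(m + 0.1, m)
  expect_lt(up$p, 1e-10)
  set.seed(8)
  a <- m + matrix(rnorm(121, 0.02, 0.05), 11, 11)
  ht <- residual_map_test(a, m)
  ref <- stats::t.test(as.vector(a - m), alternative = "greater")
  expect_equal(ht$t, unname(ref$statistic))
  expect_equal(ht$p, ref$p.value)
  ur <- residual_map_test(a, m, region = "upper_right")
  expect_equal(dim(ur$residual), c(11L, 11L))
})

test_that("the survival-threshold strategy maps perfectly at swap 0, blind to alpha", {
  spec <- toy_grid_spec(n_per_cohort = 40, seed = 9)
  cells <- list()
  for (a in c(0, 2, 4)) for (s in c(0, 0.1)) {
    pair <- make_toy_pair(spec, a, s, seed = 100 + a * 10 + s * 100)
    cells[[length(cells) + 1]] <- list(alpha = a, swap = s,
                                       source = pair$source, target = pair$target)
  }
  m <- accuracy_map(cells, "survival_threshold")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(unname(m[, "0"]), rep(1, 3))
  # column-wise constant along the batch-effect axis
  for (j in seq_len(ncol(m))) expect_equal(stats::sd(m[, j]), 0)
})

test_that("single-sample enrichment matches an independently coded oracle", {
  set.seed(10)
  expr <- matrix(rnorm(5 * 12), 5, 12,
                 dimnames = list(sprintf("S%d", 1:5), sprintf("G%02d", 1:12)))
  sets <- list(up = sprintf("G%02d", 1:10), down = sprintf("G%02d", 3:12))
  es <- ssgsea_scores(expr, sets, min_overlap = 5)
  expect_equal(es, ssgsea_brute(expr, sets), tolerance = 1e-6)
})

test_that("ssGSEA similarity is 1 for identical cohorts and penalizes disjoint profiles", {
  set.seed(11)
  expr <- matrix(rnorm(20 * 30), 20, 30,
                 dimnames = list(sprintf("S%02d", 1:20), sprintf("G%02d", 1:30)))
  sets <- list(a = sprintf("G%02d", 1:12), b = sprintf("G%02d", 15:28))
  co <- cohort(expr)
  pred <- rep(1:2, 10)
  expect_equal(ssgsea_similarity(co, co, pred, pred, sets), 1)
  # a subtype missing from one cohort is skipped with a warning; the surviving
  # subtype compares a half-cohort mean against the full-cohort mean
  expect_warning(
    sim <- ssgsea_similarity(co, co, pred, rep(1, 20), sets), "absent")
  expect_gt(sim, 0.9)
  # gene sets below the overlap floor are rejected
  expect_error(ssgsea_scores(expr, list(tiny = c("G01", "G02"))), "overlap")
})

test_that("univariate Cox coefficients track planted effects and delta weights", {
  set.seed(12)
  n <- 400
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(sprintf("S%03d", 1:n),
                                                  sprintf("P%d", 1:4)))
  beta <- c(0.8, 0, 0, 0)   # one prognostic protein, three null ones
  tt <- rweibull_ph(n, 0.01, 1, drop(x %*% beta))
  cl <- data.frame(sample_id = rownames(x), time = pmin(tt, 100),
                   event = as.integer(tt <= 100))
  co <- cohort(x, list(OS = cl))
  th <- rbind(-c(0.8, 0.2, -0.1, 0), c(0.8, 0.2, -0.1, 0))  # subtype 2 = high risk
  colnames(th) <- colnames(x)
  rep_ <- cox_coefficient_report(co, delta_weight(th), subtype = 2)
  expect_equal(rep_$cox_coef[1], 0.8, tolerance = 0.2)
  expect_lt(max(abs(rep_$cox_coef[2:4])), 0.2)   # null effects stay near zero
  expect_gt(attr(rep_, "r"), 0.9)
})

test_that("the optimal expression split maximizes the log-rank score", {
  set.seed(13)
  n <- 60
  tt <- 1:n + runif(n)
  x <- rank(tt) + rnorm(n, 0, 2)   # expression tracks survival
  res <- optimal_split_survival(x, tt, rep(1, n))
  expect_gt(res$score, 1.3)
  # brute-force the same grid
  cand <- sort(unique(x)); cand <- cand[-length(cand)]
  sizes <- vapply(cand, function(th) sum(x > th), numeric(1))
  ok <- sizes >= 6 & (n - sizes) >= 6
  brute <- max(vapply(cand[ok], function(th)
    logrank_score(x > th, tt, rep(1, n)), numeric(1)))
  expect_equal(res$score, brute)
  expect_error(optimal_split_survival(rep(1, 10), rexp(10), rep(1, 10)),
               "degenerate")
})
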