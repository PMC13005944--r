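#' Toy-grid simulator specification
#'
#' Configuration of the 121-cell toy experiment: two linearly separable
#' subtypes in 20 features, additive batch noise between source and target
#' scaled by `alpha`, and survival times strictly divided at 30 months
#' (subtype 1 survives past 30, subtype 2 dies before 30, no censoring)
#' except for a fraction of pairwise survival-time swaps that weaken the
#' subtype-survival correlation.
#'
#' @param n_per_cohort Samples per cohort (balanced subtypes; default 200).
#' @param d Feature dimension (default 20).
#' @param noise_sd SD of the per-dimension batch noise (default 0.2).
#' @param alpha_grid Noise weights, 0 to 4 step 0.4 (11 values).
#' @param swap_grid Survival swap ratios, 0 to 0.2 step 0.02 (11 values).
#' @param survival_threshold Months dividing the two subtypes' survival (30).
#' @param seed Base seed; per-cell seeds are derived from it.
#' @return List of class `toy_grid_spec`.
#' @export
toy_grid_spec <- function(n_per_cohort = 200, d = 20, noise_sd = 0.2,
                          alpha_grid = seq(0, 4, by = 0.4),
                          swap_grid = seq(0, 0.2, by = 0.02),
                          survival_threshold = 30, seed = 0) {
  stopifnot(length(alpha_grid) == 11, length(swap_grid) == 11)
  structure(list(n_per_cohort = n_per_cohort, d = d, noise_sd = noise_sd,
                 alpha_grid = alpha_grid, swap_grid = swap_grid,
                 survival_threshold = survival_threshold, seed = as.integer(seed)),
            class = "toy_grid_spec")
}

# subtype mean profiles: first half of the features elevated for subtype 1,
# second half for subtype 2, separation 0.4 on the [0, 1] scale
toy_means <- function(d) {
  half <- d %/% 2
  rbind(c(rep(0.7, half), rep(0.3, d - half)),
        c(rep(0.3, half), rep(0.7, d - half)))
}

toy_features <- function(spec, alpha, noise_mu, id_prefix) {
  n <- spec$n_per_cohort
  d <- spec$d
  labels <- rep(1:2, length.out = n)
  mu <- toy_means(d)[labels, , drop = FALSE]
  x <- pmin(pmax(mu + matrix(stats::rnorm(n * d, 0, 0.1), n, d), 0), 1)
  if (alpha > 0) {
    noise <- matrix(stats::rnorm(n * d, mean = rep(noise_mu, each = n),
                                 sd = spec$noise_sd), n, d)
    x <- x + alpha * noise
  }
  ids <- sprintf("%s%03d", id_prefix, seq_len(n))
  dimnames(x) <- list(ids, sprintf("F%02d", seq_len(d)))
  list(x = x, labels = stats::setNames(labels, ids), ids = ids)
}

toy_survival <- function(spec, labels) {
  thr <- spec$survival_threshold
  n <- length(labels)
  ifelse(labels == 1, stats::runif(n, thr, 2 * thr), stats::runif(n, 0, thr))
}

swap_survival <- function(time, labels, swap) {
  n1 <- which(labels == 1)
  n2 <- which(labels == 2)
  m <- floor(swap * min(length(n1), length(n2)))
  if (m > 0) {
    a <- sample(n1, m)
    b <- sample(n2, m)
    tmp <- time[a]; time[a] <- time[b]; time[b] <- tmp
  }
  time
}

#' Generate one toy source/target pair
#'
#' The target cohort's features are the clean subtype profiles plus
#' `alpha` times a normally distributed batch-noise field (per-dimension means
#' drawn once per dataset from U\[0, 1\], SD `noise_sd`); the source keeps the
#' clean features. Survival is strictly threshold-divided, then
#' `floor(swap * n_subtype)` random cross-subtype pairs exchange their times.
#' Both cohorts carry labels and survival; training code reads only the source
#' labels and the target survival.
#'
#' @param spec A [toy_grid_spec()].
#' @param alpha Batch-noise weight.
#' @param swap Survival swap ratio.
#' @param seed Optional seed overriding `spec$seed`.
#' @return List with `source` and `target` (`srps_cohort`s).
#' @export
make_toy_pair <- function(spec = toy_grid_spec(), alpha = 0, swap = 0, seed = NULL) {
  base_seed <- if (is.null(seed)) spec$seed else seed
  set.seed(base_seed)
  noise_mu <- stats::runif(spec$d)
  src <- toy_features(spec, 0, noise_mu, "S")
  tgt <- toy_features(spec, alpha, noise_mu, "T")
  # survival (and its swapping) is seeded by the swap level alone, so grid
  # columns share their survival draw and only the feature noise varies with
  # alpha -- the survival-threshold reference is then exactly constant along
  # the batch-effect axis
  set.seed(spec$seed + round(1e4 * swap))
  src$time <- swap_survival(toy_survival(spec, src$labels), src$labels, swap)
  tgt$time <- swap_survival(toy_survival(spec, tgt$labels), tgt$labels, swap)
  as_cohort <- function(z) {
    cl <- data.frame(sample_id = z$ids, time = z$time, event = 1L)
    cohort(z$x, list(OS = cl), z$labels)
  }
  list(source = as_cohort(src), target = as_cohort(tgt))
}

#' Generate the full 121-cell toy grid
#'
#' Cartesian product of the 11 noise weights and 11 swap ratios, each cell
#' simulated with a deterministic seed derived from `spec$seed` so any cell is
#' reproducible in isolation.
#'
#' @param spec A [toy_grid_spec()].
#' @return List of 121 elements, each `list(alpha, swap, source, target)`;
#'   ordered alpha-major (all swaps for the first alpha first).
#' @export
make_toy_grid <- function(spec = toy_grid_spec()) {
  cells <- list()
  idx <- 0L
  for (ai in seq_along(spec$alpha_grid)) {
    for (si in seq_along(spec$swap_grid)) {
      idx <- idx + 1L
      cell_seed <- spec$seed + 1009L * ai + 37L * si
      pair <- make_toy_pair(spec, spec$alpha_grid[ai], spec$swap_grid[si],
                            seed = cell_seed)
      cells[[idx]] <- list(alpha = spec$alpha_grid[ai], swap = spec$swap_grid[si],
                           source = pair$source, target = pair$target)
    }
  }
  cells
}

#' Benchmark simulator specification
#'
#' Configuration of the batch-effect benchmark: 1000 samples, 1000 features,
#' 3 subtypes split over 2 batches, multiplicative log-normal per-feature
#' batch factors applied to the second batch (location/scale 0.01 simulates no
#' batch effect, 2 a large one), and Weibull proportional-hazards survival
#' with baseline cumulative hazard `lambda * t^gamma` and per-subtype
#' log-hazard offsets.
#'
#' @param n_samples Total samples (default 1000, split evenly into 2 batches).
#' @param n_features Features (default 1000).
#' @param k Subtypes (default 3).
#' @param batch_loc,batch_scale Log-normal location and scale of the batch
#'   factors (0.01 = negligible, 2 = large).
#' @param de_prob Probability that a feature is differential for a subtype
#'   (default 0.02: a sparse signature, some tens of informative proteins per
#'   subtype, as proteomic subtype signatures typically are).
#' @param de_sd Log-scale SD of subtype effects on differential features.
#' @param noise_sd Log-scale biological noise SD on the per-sample Poisson
#'   mean (default 0.4, a typical between-sample coefficient of variation).
#' @param weibull_lambda,weibull_gamma Weibull coefficients (0.005, 0.5).
#' @param subtype_log_hazard Strictly increasing k-vector of log-hazards
#'   (default 0, 1.5, 3.0: subtype 1 has the best prognosis, and the implied
#'   60-month survival of roughly 0.96 / 0.84 / 0.46 gives the clearly
#'   ordered prognoses a subtype benchmark needs within the RMST horizon).
#' @param censor_admin_time Administrative censoring horizon in months (60).
#' @param seed Seed.
#' @return List of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_samples = 1000, n_features = 1000, k = 3,
                           batch_loc = 0.01, batch_scale = 0.01,
                           de_prob = 0.02, de_sd = 0.8, noise_sd = 0.4,
                           weibull_lambda = 0.005, weibull_gamma = 0.5,
                           subtype_log_hazard = c(0, 1.5, 3.0),
                           censor_admin_time = 60, seed = 0) {
  stopifnot(length(subtype_log_hazard) == k, !is.unsorted(subtype_log_hazard, strictly = TRUE))
  structure(list(n_samples = n_samples, n_features = n_features, k = k,
                 batch_loc = batch_loc, batch_scale = batch_scale,
                 de_prob = de_prob, de_sd = de_sd, noise_sd = noise_sd,
                 weibull_lambda = weibull_lambda, weibull_gamma = weibull_gamma,
                 subtype_log_hazard = subtype_log_hazard,
                 censor_admin_time = censor_admin_time, seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Sample Weibull proportional-hazards survival times
#'
#' Inverse-CDF draw from the cumulative hazard
#' `H(t) = lambda * t^gamma * exp(log_hazard)`:
#' `t = (-log(U) / (lambda * exp(log_hazard)))^(1/gamma)`.
#'
#' @param n Number of draws.
#' @param lambda,gamma Weibull coefficients.
#' @param log_hazard Per-draw log-hazard offset (scalar or length n).
#' @return Uncensored event times.
#' @export
rweibull_ph <- function(n, lambda, gamma, log_hazard = 0) {
  u <- stats::runif(n)
  (-log(u) / (lambda * exp(log_hazard)))^(1 / gamma)
}

#' Generate the benchmark source/target pair
#'
#' Abundances follow a count model: per-feature log-normal means built from a
#' shared baseline, per-subtype effects on a random subset of features,
#' multiplicative batch factors (log-normal with location `batch_loc` and
#' scale `batch_scale`, randomly sign-inverted per feature) applied to
#' batch 2, and log-normal biological noise; the observation is a Poisson
#' draw, and a zero is emitted as a missing value the way a low-abundance
#' protein goes undetected in a run. The interesting consequence for
#' cohort transfer: a per-cohort affine normalization removes the batch
#' factors' location shifts, but down-scaled features lose their
#' signal-to-noise (counting noise dominates, detections drop below the
#' filter), so a large batch effect degrades a source-trained classifier in
#' a way no global correction can undo. Feed the pair through
#' [preprocess_pair()] before training, exactly like a real cohort pair.
#' Survival follows the Weibull proportional-hazards model with
#' administrative censoring. Batch 1 becomes the labeled source cohort,
#' batch 2 the target.
#'
#' @param spec A [benchmark_spec()].
#' @return List with `source` and `target` (`srps_cohort`s, both carrying
#'   labels and OS survival; target labels are for evaluation only).
#' @export
make_benchmark_pair <- function(spec = benchmark_spec()) {
  set.seed(spec$seed)
  n <- spec$n_samples; d <- spec$n_features; k <- spec$k
  batch <- rep(1:2, length.out = n)
  subtype <- sample(rep(seq_len(k), length.out = n))
  mu <- stats::rnorm(d, mean = 1.5, sd = 1)
  de <- matrix(stats::rnorm(k * d, 0, spec$de_sd) *
                 (matrix(stats::runif(k * d), k, d) < spec$de_prob), k, d)
  log_fac <- stats::rnorm(d, spec$batch_loc, spec$batch_scale) *
    sample(c(-1, 1), d, replace = TRUE)
  lam <- exp(matrix(mu, n, d, byrow = TRUE) + de[subtype, , drop = FALSE] +
               outer(batch == 2, log_fac) +
               matrix(stats::rnorm(n * d, 0, spec$noise_sd), n, d))
  x <- matrix(stats::rpois(n * d, lam), n, d)
  x[x == 0] <- NA_real_  # a zero count is a non-detection, as in label-free MS
  ids <- sprintf("B%d_%04d", batch, seq_len(n))
  dimnames(x) <- list(ids, sprintf("P%04d", seq_len(d)))
  t_raw <- rweibull_ph(n, spec$weibull_lambda, spec$weibull_gamma,
                       spec$subtype_log_hazard[subtype])
  event <- as.integer(t_raw <= spec$censor_admin_time)
  time <- pmin(t_raw, spec$censor_admin_time)
  as_cohort <- function(sel) {
    cl <- data.frame(sample_id = ids[sel], time = time[sel], event = event[sel])
    cohort(x[sel, , drop = FALSE], list(OS = cl),
           stats::setNames(subtype[sel], ids[sel]))
  }
  list(source = as_cohort(batch == 1), target = as_cohort(batch == 2))
}
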