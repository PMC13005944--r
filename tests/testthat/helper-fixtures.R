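# Shared fixture builders; everything is generated in code at test time.

# a tiny labeled cohort with exponential survival, k subtypes
tiny_cohort <- function(n = 20, d = 6, k = 2, seed = 42, prefix = "S") {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d,
              dimnames = list(sprintf("%s%02d", prefix, 1:n), sprintf("P%d", 1:d)))
  labels <- rep(seq_len(k), length.out = n)
  time <- round(rexp(n, rate = 0.02), 2)
  cl <- data.frame(sample_id = rownames(x), time = time,
                   event = rbinom(n, 1, 0.7))
  cohort(x, list(OS = cl), stats::setNames(labels, rownames(x)))
}

# expression matrix with controllable missingness
random_expr <- function(n, d, na_frac = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(round(rnorm(n * d, 10, 2), 4), n, d,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("P%02d", 1:d)))
  if (na_frac > 0) x[sample(length(x), round(na_frac * length(x)))] <- NA
  x
}

# brute-force C-index over all ordered pairs (independent oracle)
cindex_brute <- function(score, times, events) {
  n <- length(score)
  num <- 0
  den <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ti <- times[i]; tj <- times[j]; ei <- events[i]; ej <- events[j]
    if (ti == tj) {
      if (ei == 1 && ej == 1) { den <- den + 1; num <- num + 0.5 }
      next
    }
    first <- if (ti < tj) i else j
    second <- if (ti < tj) j else i
    if (events[first] != 1) next
    den <- den + 1
    if (score[first] < score[second]) num <- num + 1
    else if (score[first] == score[second]) num <- num + 0.5
  }
  num / den
}

# independent single-sample enrichment implementation (plain loops)
ssgsea_brute <- function(expr, gene_sets, alpha = 0.25) {
  out <- matrix(NA_real_, nrow(expr), length(gene_sets),
                dimnames = list(rownames(expr), names(gene_sets)))
  n <- ncol(expr)
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, ]
    r <- rank(x, ties.method = "average")
    ord <- order(x, decreasing = TRUE)
    for (j in seq_along(gene_sets)) {
      idx <- which(colnames(expr) %in% gene_sets[[j]])
      pin <- 0; pout <- 0; es <- 0
      win_tot <- sum(r[idx]^alpha)
      n_out <- n - length(idx)
      for (pos in seq_len(n)) {
        g <- ord[pos]
        if (g %in% idx) pin <- pin + r[g]^alpha / win_tot
        else pout <- pout + 1 / n_out
        es <- es + (pin - pout)
      }
      out[i, j] <- es
    }
  }
  out
}
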