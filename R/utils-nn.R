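# Small neural-network primitives shared by the SRPS classifier, the reward
# baseline and the DNN/DANN baselines. Everything is full-batch matrix algebra
# with analytic gradients; parameters live in plain named lists.

softmax_rows <- function(logits) {
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  e / rowSums(e)
}

one_hot <- function(labels, k) {
  n <- length(labels)
  m <- matrix(0, n, k)
  m[cbind(seq_len(n), as.integer(labels))] <- 1
  m
}

clip_prob <- function(p, eps = 1e-12) pmax(p, eps)

# inverted dropout: scales kept units by 1/(1-rate) so inference needs no scaling
dropout_mask <- function(n, d, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(n * d, 1L, 1 - rate) / (1 - rate), n, d)
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Adam over a named list of numeric arrays
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# 3-layer perceptron used as the reward-baseline estimator: two sigmoid hidden
# layers of n_h units and a scalar linear output.
baseline_init <- function(d, n_h) {
  list(W1 = glorot(d, n_h), b1 = rep(0, n_h),
       W2 = glorot(n_h, n_h), b2 = rep(0, n_h),
       W3 = glorot(n_h, 1), b3 = 0)
}

baseline_forward <- function(par, x) {
  h1 <- sigmoid(sweep(x %*% par$W1, 2, par$b1, "+"))
  h2 <- sigmoid(sweep(h1 %*% par$W2, 2, par$b2, "+"))
  b <- drop(h2 %*% par$W3) + par$b3
  list(b = b, h1 = h1, h2 = h2)
}

# backprop given d(loss)/d(output) as a length-n vector
baseline_backward <- function(par, x, fwd, db) {
  db <- matrix(db, ncol = 1)
  gW3 <- t(fwd$h2) %*% db
  gb3 <- sum(db)
  dh2 <- (db %*% t(par$W3)) * fwd$h2 * (1 - fwd$h2)
  gW2 <- t(fwd$h1) %*% dh2
  gb2 <- colSums(dh2)
  dh1 <- (dh2 %*% t(par$W2)) * fwd$h1 * (1 - fwd$h1)
  gW1 <- t(x) %*% dh1
  gb1 <- colSums(dh1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}
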