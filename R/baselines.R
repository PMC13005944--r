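#' DNN baseline configuration
#'
#' Feed-forward classifier: one hidden layer, a dropout layer, and a linear
#' prediction layer, trained with cross-entropy and Adam on the labeled
#' source cohort only.
#'
#' @param hidden_dim Hidden width (default 20).
#' @param dropout Dropout rate on the hidden layer (default 0.8).
#' @param lr Adam learning rate (default 0.01).
#' @param epochs Full-batch epochs (default 2000).
#' @param seed Seed.
#' @return List of class `dnn_config`.
#' @export
dnn_config <- function(hidden_dim = 20, dropout = 0.8, lr = 0.01,
                       epochs = 2000, seed = 0) {
  stopifnot(hidden_dim > 0, dropout >= 0, dropout < 1, lr > 0, epochs > 0)
  structure(list(hidden_dim = as.integer(hidden_dim), dropout = dropout,
                 lr = lr, epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "dnn_config")
}

#' Train the supervised DNN baseline
#'
#' @param source Labeled `srps_cohort`.
#' @param cfg A [dnn_config()].
#' @return Object of class `dnn_model` with a [predict()] method
#'   (`type = "class"` or `"prob"`).
#' @export
train_dnn <- function(source, cfg = dnn_config()) {
  if (is.null(source$labels)) stop("source cohort must be labeled")
  x <- source$expr
  k <- max(source$labels)
  y <- one_hot(source$labels, k)
  set.seed(cfg$seed)
  h <- cfg$hidden_dim
  par <- list(W1 = glorot(ncol(x), h), b1 = rep(0, h),
              W2 = glorot(h, k), b2 = rep(0, k))
  opt <- adam_init(par)
  n <- nrow(x)
  for (ep in seq_len(cfg$epochs)) {
    H <- pmax(sweep(x %*% par$W1, 2, par$b1, "+"), 0)
    Hd <- H
    mask <- dropout_mask(n, h, cfg$dropout)
    if (!is.null(mask)) Hd <- H * mask
    P <- softmax_rows(sweep(Hd %*% par$W2, 2, par$b2, "+"))
    dl <- (P - y) / n
    g <- list(W2 = t(Hd) %*% dl, b2 = colSums(dl))
    dH <- dl %*% t(par$W2)
    if (!is.null(mask)) dH <- dH * mask
    dH <- dH * (H > 0)
    g$W1 <- t(x) %*% dH
    g$b1 <- colSums(dH)
    stp <- adam_step(opt, par, g, cfg$lr)
    opt <- stp$state
    par <- stp$params
  }
  structure(list(par = par, k = k, features = colnames(x), config = cfg),
            class = "dnn_model")
}

dnn_forward <- function(par, x) {
  H <- pmax(sweep(x %*% par$W1, 2, par$b1, "+"), 0)
  softmax_rows(sweep(H %*% par$W2, 2, par$b2, "+"))
}

#' @param object A `dnn_model`.
#' @param newdata Feature matrix.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @rdname train_dnn
#' @export
predict.dnn_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$par$W1)) stop("feature dimension mismatch")
  p <- dnn_forward(object$par, newdata)
  if (type == "prob") p else max.col(p, ties.method = "first")
}

#' DANN baseline configuration
#'
#' Adversarial domain-adaptation network: an encoder shared by a task
#' classifier (cross-entropy on the labeled source) and a domain classifier
#' (source vs target), with a gradient-reversal layer scaling `-grl_weight`
#' into the encoder so it learns domain-invariant features.
#'
#' @param encoder_hidden Encoder width (default 20).
#' @param classifier_hidden Head hidden width (default 10).
#' @param n_layers 1 or 2 layers for the encoder and heads jointly.
#' @param dropout Dropout on the encoded representation, 0 or 0.3 (default
#'   0.3, the better-validating option).
#' @param lr Adam learning rate (default 0.01).
#' @param grl_weight Gradient-reversal scale (default 1).
#' @param epochs Full-batch epochs (default 2000).
#' @param seed Seed.
#' @return List of class `dann_config`.
#' @export
dann_config <- function(encoder_hidden = 20, classifier_hidden = 10,
                        n_layers = 2, dropout = 0.3, lr = 0.01, grl_weight = 1,
                        epochs = 2000, seed = 0) {
  stopifnot(n_layers %in% c(1, 2), dropout >= 0, dropout < 1)
  structure(list(encoder_hidden = as.integer(encoder_hidden),
                 classifier_hidden = as.integer(classifier_hidden),
                 n_layers = as.integer(n_layers), dropout = dropout, lr = lr,
                 grl_weight = grl_weight, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "dann_config")
}

dann_encode <- function(par, x, n_layers) {
  z <- pmax(sweep(x %*% par$We1, 2, par$be1, "+"), 0)
  if (n_layers == 2) z <- pmax(sweep(z %*% par$We2, 2, par$be2, "+"), 0)
  z
}

# head forward: optional hidden relu layer (n_layers == 2) then linear softmax
head_forward <- function(W1, b1, W2, b2, z, two_layer) {
  if (two_layer) {
    h <- pmax(sweep(z %*% W1, 2, b1, "+"), 0)
    list(p = softmax_rows(sweep(h %*% W2, 2, b2, "+")), h = h)
  } else {
    list(p = softmax_rows(sweep(z %*% W2, 2, b2, "+")), h = NULL)
  }
}

#' Train the adversarial domain-adaptation (DANN) baseline
#'
#' @param source Labeled `srps_cohort`.
#' @param target Unlabeled `srps_cohort` sharing the source's feature space.
#' @param cfg A [dann_config()].
#' @return Object of class `dann_model` with a [predict()] method.
#' @export
train_dann <- function(source, target, cfg = dann_config()) {
  if (is.null(source$labels)) stop("source cohort must be labeled")
  xs <- source$expr; xt <- target$expr
  if (!identical(colnames(xs), colnames(xt)))
    stop("source and target must share an identically ordered feature space")
  k <- max(source$labels)
  ys <- one_hot(source$labels, k)
  x <- rbind(xs, xt)
  dom <- one_hot(rep(1:2, c(nrow(xs), nrow(xt))), 2)
  is_src <- seq_len(nrow(xs))
  set.seed(cfg$seed)
  eh <- cfg$encoder_hidden; ch <- cfg$classifier_hidden
  two <- cfg$n_layers == 2
  par <- list(We1 = glorot(ncol(x), eh), be1 = rep(0, eh))
  if (two) { par$We2 <- glorot(eh, eh); par$be2 <- rep(0, eh) }
  init_head <- function(k_out) {
    if (two) list(W1 = glorot(eh, ch), b1 = rep(0, ch),
                  W2 = glorot(ch, k_out), b2 = rep(0, k_out))
    else list(W1 = NULL, b1 = NULL, W2 = glorot(eh, k_out), b2 = rep(0, k_out))
  }
  task <- init_head(k)
  domh <- init_head(2)
  flat <- function(task, domh) {
    c(par,
      stats::setNames(Filter(Negate(is.null), task), paste0("t_", names(Filter(Negate(is.null), task)))),
      stats::setNames(Filter(Negate(is.null), domh), paste0("d_", names(Filter(Negate(is.null), domh)))))
  }
  params <- flat(task, domh)
  opt <- adam_init(params)
  n_all <- nrow(x); n_src <- nrow(xs)

  head_backward <- function(head, z, fwd, dlogit) {
    g <- list()
    if (two) {
      g$W2 <- t(fwd$h) %*% dlogit; g$b2 <- colSums(dlogit)
      dh <- (dlogit %*% t(head$W2)) * (fwd$h > 0)
      g$W1 <- t(z) %*% dh; g$b1 <- colSums(dh)
      dz <- dh %*% t(head$W1)
    } else {
      g$W2 <- t(z) %*% dlogit; g$b2 <- colSums(dlogit)
      dz <- dlogit %*% t(head$W2)
    }
    list(g = g, dz = dz)
  }

  for (ep in seq_len(cfg$epochs)) {
    h1 <- pmax(sweep(x %*% params$We1, 2, params$be1, "+"), 0)
    z <- if (two) pmax(sweep(h1 %*% params$We2, 2, params$be2, "+"), 0) else h1
    zd <- z
    mask <- dropout_mask(n_all, ncol(z), cfg$dropout)
    if (!is.null(mask)) zd <- z * mask
    task_par <- list(W1 = params$t_W1, b1 = params$t_b1, W2 = params$t_W2, b2 = params$t_b2)
    dom_par <- list(W1 = params$d_W1, b1 = params$d_b1, W2 = params$d_W2, b2 = params$d_b2)
    ft <- head_forward(task_par$W1, task_par$b1, task_par$W2, task_par$b2,
                       zd[is_src, , drop = FALSE], two)
    fd <- head_forward(dom_par$W1, dom_par$b1, dom_par$W2, dom_par$b2, zd, two)

    dlt <- (ft$p - ys) / n_src
    bt <- head_backward(task_par, zd[is_src, , drop = FALSE], ft, dlt)
    dld <- (fd$p - dom) / n_all
    bd <- head_backward(dom_par, zd, fd, dld)

    # gradient reversal: encoder sees task gradient minus grl_weight x domain gradient
    dz <- -cfg$grl_weight * bd$dz
    dz[is_src, ] <- dz[is_src, , drop = FALSE] + bt$dz
    if (!is.null(mask)) dz <- dz * mask
    g <- list()
    if (two) {
      dz2 <- dz * (z > 0)
      g$We2 <- t(h1) %*% dz2; g$be2 <- colSums(dz2)
      dh1 <- (dz2 %*% t(params$We2)) * (h1 > 0)
    } else {
      dh1 <- dz * (h1 > 0)
    }
    g$We1 <- t(x) %*% dh1; g$be1 <- colSums(dh1)
    for (nm in names(bt$g)) g[[paste0("t_", nm)]] <- bt$g[[nm]]
    for (nm in names(bd$g)) g[[paste0("d_", nm)]] <- bd$g[[nm]]
    stp <- adam_step(opt, params, g, cfg$lr)
    opt <- stp$state
    params <- stp$params
  }
  structure(list(par = params, k = k, two = two, features = colnames(x),
                 config = cfg),
            class = "dann_model")
}

dann_task_proba <- function(object, x) {
  p <- object$par
  z <- dann_encode(list(We1 = p$We1, be1 = p$be1, We2 = p$We2, be2 = p$be2),
                   x, if (object$two) 2 else 1)
  head_forward(p$t_W1, p$t_b1, p$t_W2, p$t_b2, z, object$two)$p
}

#' Domain-classifier probabilities of a trained DANN
#'
#' Diagnostic: accuracy near 0.5 on held-out samples indicates successful
#' domain confusion.
#'
#' @param object A `dann_model`.
#' @param newdata Feature matrix.
#' @return n x 2 matrix of source/target probabilities.
#' @export
dann_domain_proba <- function(object, newdata) {
  p <- object$par
  z <- dann_encode(list(We1 = p$We1, be1 = p$be1, We2 = p$We2, be2 = p$be2),
                   as.matrix(newdata), if (object$two) 2 else 1)
  head_forward(p$d_W1, p$d_b1, p$d_W2, p$d_b2, z, object$two)$p
}

#' @param object A `dann_model`.
#' @param newdata Feature matrix.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @rdname train_dann
#' @export
predict.dann_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$par$We1)) stop("feature dimension mismatch")
  p <- dann_task_proba(object, newdata)
  if (type == "prob") p else max.col(p, ties.method = "first")
}
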