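# Single-hidden-layer feedforward classifier: tangent-sigmoid hidden layer,
# softmax output, cross-entropy loss with per-class weights, full-batch Adam
# with early stopping on a validation set. hidden = 0 degenerates to
# multinomial logistic regression. Deterministic given the seed.

mlp_fit <- function(x, y, hidden, class_weights = NULL, val_idx = NULL,
                    max_iter = 150L, learn_rate = 0.02, patience = 12L,
                    l2 = 1e-4, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  classes <- levels(y)
  K <- length(classes)
  if (K < 2) abort("training data contains a single class")
  n <- nrow(x); d <- ncol(x)

  ctr <- colMeans(x)
  scl <- apply(x, 2, sd); scl[scl < 1e-12] <- 1
  X <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  if (is.null(class_weights)) class_weights <- rep(1, K)
  w <- class_weights[as.integer(y)]

  # a handful of validation samples is too noisy to drive early stopping;
  # below this size the training loss is monitored instead
  if (!is.null(val_idx) && length(val_idx) < 50L) val_idx <- NULL
  if (!is.null(val_idx) && length(val_idx) > 0) {
    Xv <- X[val_idx, , drop = FALSE]; Yv <- Y[val_idx, , drop = FALSE]
    wv <- w[val_idx]
    Xt <- X[-val_idx, , drop = FALSE]; Yt <- Y[-val_idx, , drop = FALSE]
    wt <- w[-val_idx]
  } else {
    Xt <- X; Yt <- Y; wt <- w
    Xv <- NULL
  }
  wt <- wt / sum(wt)

  set.seed(seed)
  H <- as.integer(hidden)
  if (H > 0) {
    W1 <- matrix(rnorm(d * H, sd = sqrt(1 / max(d, 1))), d, H)
    b1 <- numeric(H)
    W2 <- matrix(rnorm(H * K, sd = sqrt(1 / H)), H, K)
    b2 <- numeric(K)
    params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  } else {
    params <- list(W2 = matrix(rnorm(d * K, sd = sqrt(1 / max(d, 1))), d, K),
                   b2 = numeric(K))
  }

  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  forward <- function(p, X) {
    if (H > 0) {
      Hm <- tanh(sweep(X %*% p$W1, 2, p$b1, "+"))
      S <- sweep(Hm %*% p$W2, 2, p$b2, "+")
      list(H = Hm, P = softmax_rows(S))
    } else {
      list(H = NULL, P = softmax_rows(sweep(X %*% p$W2, 2, p$b2, "+")))
    }
  }
  ce_loss <- function(P, Y, w) {
    -sum(w * rowSums(Y * log(P + 1e-12))) / sum(w)
  }

  best <- params; best_loss <- Inf; stall <- 0L; trace <- numeric(0)
  # early stopping is armed only after a burn-in, so the optimizer's
  # initial plateau cannot truncate training
  min_iter <- min(max_iter, max(40L, 2L * patience))
  for (it in seq_len(max_iter)) {
    fw <- forward(params, Xt)
    dS <- (fw$P - Yt) * wt
    if (H > 0) {
      gW2 <- crossprod(fw$H, dS) + l2 * params$W2
      gb2 <- colSums(dS)
      dH <- (dS %*% t(params$W2)) * (1 - fw$H^2)
      gW1 <- crossprod(Xt, dH) + l2 * params$W1
      gb1 <- colSums(dH)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    } else {
      grads <- list(W2 = crossprod(Xt, dS) + l2 * params$W2, b2 = colSums(dS))
    }
    for (nm in names(params)) {
      mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
      vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- mom[[nm]] / (1 - beta1^it)
      vhat <- vel[[nm]] / (1 - beta2^it)
      params[[nm]] <- params[[nm]] - learn_rate * mhat / (sqrt(vhat) + eps)
    }
    mon <- if (!is.null(Xv)) {
      ce_loss(forward(params, Xv)$P, Yv, wv)
    } else {
      ce_loss(forward(params, Xt)$P, Yt, wt)
    }
    trace <- c(trace, mon)
    if (mon < best_loss - 1e-6) {
      best_loss <- mon; best <- params; stall <- 0L
    } else {
      stall <- stall + 1L
      if (it >= min_iter && stall >= patience) break
    }
  }

  structure(
    list(params = best, hidden = H, classes = classes, center = ctr,
         scale = scl, loss = best_loss, trace = trace, seed = seed,
         version = "1"),
    class = "acu_mlp"
  )
}

# degenerate fit: always emits (almost) probability 1 for one class;
# used when every training epoch of a cascade period has the same label
# (e.g. the early-night period of a corpus where no subject was asleep
# before epoch 20)
constant_mlp <- function(classes, which_class, d) {
  b2 <- rep(0, length(classes))
  b2[match(which_class, classes)] <- 12
  structure(
    list(params = list(W2 = matrix(0, d, length(classes)), b2 = b2),
         hidden = 0L, classes = classes, center = numeric(d),
         scale = rep(1, d), loss = NA_real_, trace = numeric(0),
         seed = NA_integer_, constant = which_class, version = "1"),
    class = "acu_mlp"
  )
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

mlp_predict <- function(model, x) {
  X <- sweep(sweep(as.matrix(x), 2, model$center), 2, model$scale, "/")
  p <- model$params
  if (model$hidden > 0) {
    Hm <- tanh(sweep(X %*% p$W1, 2, p$b1, "+"))
    P <- softmax_rows(sweep(Hm %*% p$W2, 2, p$b2, "+"))
  } else {
    P <- softmax_rows(sweep(X %*% p$W2, 2, p$b2, "+"))
  }
  colnames(P) <- model$classes
  P
}
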