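# Hand-authored recurrent network numerics: two stacked LSTM layers, an
# optional temporal soft-attention block, a linear context bottleneck and a
# linear output head, with exact backpropagation through time and an Adam
# optimizer. Vectorized over the batch dimension; gate order in the fused
# 4h-wide kernels is (input, forget, candidate, output). One bias vector per
# layer (single-bias convention), so a layer holds 4h(d + h + 1) parameters.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot_uniform <- function(fan_in, fan_out, nrow, ncol) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

orthogonal_init <- function(h, ncols) {
  # per-gate h x h orthogonal blocks, column-bound
  blocks <- lapply(seq_len(ncols / h), function(i) {
    qrd <- qr(matrix(stats::rnorm(h * h), h, h))
    q <- qr.Q(qrd)
    q * sign(diag(qr.R(qrd)))[col(q)]
  })
  do.call(cbind, blocks)
}

init_params <- function(spec, seed = 1L) {
  set.seed(seed)
  d <- spec$input_dim; h <- spec$hidden; ctx <- spec$context_dim
  head_dim <- ctx + if (spec$include_mg_cluster) 2L else 0L
  b1 <- numeric(4 * h); b1[(h + 1):(2 * h)] <- 1  # forget-gate bias 1
  b2 <- numeric(4 * h); b2[(h + 1):(2 * h)] <- 1
  p <- list(
    W1 = glorot_uniform(d, 4 * h, d, 4 * h),
    U1 = orthogonal_init(h, 4 * h),
    b1 = b1,
    W2 = glorot_uniform(h, 4 * h, h, 4 * h),
    U2 = orthogonal_init(h, 4 * h),
    b2 = b2,
    Wc = glorot_uniform(h, ctx, h, ctx),
    bc = numeric(ctx),
    Wo = glorot_uniform(head_dim, 1, head_dim, 1),
    bo = 0
  )
  if (spec$variant == "attention") {
    p$wa <- glorot_uniform(h, 1, h, 1)
    p$ba <- 0
  }
  p
}

# forward pass of one LSTM layer over a list of per-step input matrices
lstm_layer_forward <- function(xs, W, U, b) {
  tx <- length(xs)
  n <- nrow(xs[[1]])
  h <- ncol(U)
  h <- h / 4
  H <- matrix(0, n, h); C <- matrix(0, n, h)
  bmat <- matrix(b, n, 4 * h, byrow = TRUE)
  # input contributions for all steps in one multiply
  XW <- do.call(rbind, xs) %*% W
  cache <- vector("list", tx)
  hs <- vector("list", tx)
  ifo <- c(1:(2 * h), (3 * h + 1):(4 * h))  # sigmoid gates in one call
  for (t in seq_len(tx)) {
    G <- XW[((t - 1) * n + 1):(t * n), , drop = FALSE] + H %*% U + bmat
    S <- sigmoid(G[, ifo, drop = FALSE])
    i <- S[, 1:h, drop = FALSE]
    f <- S[, (h + 1):(2 * h), drop = FALSE]
    g <- tanh(G[, (2 * h + 1):(3 * h), drop = FALSE])
    o <- S[, (2 * h + 1):(3 * h), drop = FALSE]
    c_prev <- C
    C <- f * C + i * g
    tc <- tanh(C)
    h_prev <- H
    H <- o * tc
    cache[[t]] <- list(x = xs[[t]], i = i, f = f, g = g, o = o,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
    hs[[t]] <- H
  }
  list(hs = hs, cache = cache)
}

# backprop through one LSTM layer; dhs: per-step grads w.r.t. layer outputs
lstm_layer_backward <- function(cache, dhs, W, U) {
  tx <- length(cache)
  n <- nrow(cache[[1]]$x)
  h <- ncol(cache[[1]]$i)
  dU <- matrix(0, h, 4 * h)
  dGs <- vector("list", tx)
  dh_acc <- matrix(0, n, h)
  dc <- matrix(0, n, h)
  tU <- t(U)
  for (t in rev(seq_len(tx))) {
    k <- cache[[t]]
    dh <- dh_acc + if (is.null(dhs[[t]])) 0 else dhs[[t]]
    do <- dh * k$tc
    dct <- dh * k$o * (1 - k$tc^2) + dc
    di <- dct * k$g
    dg <- dct * k$i
    df <- dct * k$c_prev
    dc <- dct * k$f
    dG <- matrix(0, n, 4 * h)
    dG[, 1:h] <- di * k$i * (1 - k$i)
    dG[, (h + 1):(2 * h)] <- df * k$f * (1 - k$f)
    dG[, (2 * h + 1):(3 * h)] <- dg * (1 - k$g^2)
    dG[, (3 * h + 1):(4 * h)] <- do * k$o * (1 - k$o)
    dGs[[t]] <- dG
    dU <- dU + crossprod(k$h_prev, dG)
    dh_acc <- dG %*% tU
  }
  # batched kernel/bias grads and input grads across all steps
  dGall <- do.call(rbind, dGs)
  Xall <- do.call(rbind, lapply(cache, `[[`, "x"))
  dW <- crossprod(Xall, dGall)
  db <- colSums(dGall)
  dXall <- dGall %*% t(W)
  dxs <- lapply(seq_len(tx), function(t)
    dXall[((t - 1) * n + 1):(t * n), , drop = FALSE])
  list(dW = dW, dU = dU, db = db, dxs = dxs)
}

row_softmax <- function(S) {
  S <- S - apply(S, 1, max)  # shift invariance: numerical stabilization
  E <- exp(S)
  E / rowSums(E)
}

# full forward pass; training = TRUE draws fresh inverted-dropout masks
nn_forward <- function(params, spec, x, side = NULL, training = FALSE) {
  n <- dim(x)[1]; tx <- dim(x)[2]; d <- dim(x)[3]
  xs <- lapply(seq_len(tx), function(t) matrix(x[, t, ], n, d)) # n x d each
  l1 <- lstm_layer_forward(xs, params$W1, params$U1, params$b1)
  p <- spec$dropout
  keep <- 1 - p
  if (training && p > 0) {
    m1 <- lapply(seq_len(tx), function(t)
      matrix((stats::runif(n * spec$hidden) < keep) / keep, n, spec$hidden))
    h1d <- lapply(seq_len(tx), function(t) l1$hs[[t]] * m1[[t]])
  } else {
    m1 <- NULL
    h1d <- l1$hs
  }
  l2 <- lstm_layer_forward(h1d, params$W2, params$U2, params$b2)
  if (training && p > 0) {
    m2 <- lapply(seq_len(tx), function(t)
      matrix((stats::runif(n * spec$hidden) < keep) / keep, n, spec$hidden))
    a <- lapply(seq_len(tx), function(t) l2$hs[[t]] * m2[[t]])
  } else {
    m2 <- NULL
    a <- l2$hs
  }
  alpha <- NULL
  if (spec$variant == "attention") {
    S <- vapply(seq_len(tx), function(t)
      drop(a[[t]] %*% params$wa) + params$ba, numeric(n))
    S <- matrix(S, n, tx)
    alpha <- row_softmax(S)
    z <- Reduce(`+`, lapply(seq_len(tx), function(t) alpha[, t] * a[[t]]))
  } else {
    z <- a[[tx]]
  }
  ctx <- sweep(z %*% params$Wc, 2, params$bc, "+")
  feat <- if (spec$include_mg_cluster) cbind(ctx, side) else ctx
  yhat <- drop(feat %*% params$Wo) + params$bo
  list(yhat = yhat, alpha = alpha,
       cache = list(l1 = l1, l2 = l2, m1 = m1, m2 = m2, a = a,
                    alpha = alpha, z = z, ctx = ctx, feat = feat, xs = xs))
}

# full backward pass from dL/dyhat; returns grads in the params layout
nn_backward <- function(params, spec, cache, dyhat) {
  n <- length(dyhat); tx <- length(cache$a); h <- spec$hidden
  ctxd <- spec$context_dim
  dyhat <- matrix(dyhat, n, 1)
  g <- list()
  g$Wo <- crossprod(cache$feat, dyhat)
  g$bo <- sum(dyhat)
  dfeat <- dyhat %*% t(params$Wo)
  dctx <- dfeat[, seq_len(ctxd), drop = FALSE]
  g$Wc <- crossprod(cache$z, dctx)
  g$bc <- colSums(dctx)
  dz <- dctx %*% t(params$Wc)

  da <- vector("list", tx)
  if (spec$variant == "attention") {
    alpha <- cache$alpha
    a <- cache$a
    dalpha <- vapply(seq_len(tx), function(t) rowSums(a[[t]] * dz),
                     numeric(n))
    dalpha <- matrix(dalpha, n, tx)
    dS <- alpha * (dalpha - rowSums(alpha * dalpha))
    g$wa <- matrix(0, h, 1)
    g$ba <- sum(dS)
    for (t in seq_len(tx)) {
      da[[t]] <- alpha[, t] * dz + dS[, t] %*% t(params$wa)
      g$wa <- g$wa + crossprod(a[[t]], dS[, t, drop = FALSE])
    }
  } else {
    da[[tx]] <- dz
  }
  # grads flow through the second dropout masks into layer-2 outputs
  if (!is.null(cache$m2)) {
    for (t in seq_len(tx))
      if (!is.null(da[[t]])) da[[t]] <- da[[t]] * cache$m2[[t]]
  }
  bl2 <- lstm_layer_backward(cache$l2$cache, da, params$W2, params$U2)
  g$W2 <- bl2$dW; g$U2 <- bl2$dU; g$b2 <- bl2$db
  dh1 <- bl2$dxs
  if (!is.null(cache$m1)) {
    for (t in seq_len(tx)) dh1[[t]] <- dh1[[t]] * cache$m1[[t]]
  }
  bl1 <- lstm_layer_backward(cache$l1$cache, dh1, params$W1, params$U1)
  g$W1 <- bl1$dW; g$U1 <- bl1$dU; g$b1 <- bl1$db
  g[names(params)]
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.001,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

mse_loss <- function(yhat, y) mean((yhat - y)^2)
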