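## Internal neural-network machinery: a one-conv-layer CNN (ReLU, windowed
## max pooling, one ReLU dense hidden layer, linear multi-task output) and
## a dense MLP, with exact analytic backpropagation, plus an Adam
## optimiser. Kept deliberately small -- these exist so trained models
## satisfying the sequence-model contract (batched scalar predict + exact
## input gradient) can be built and interrogated without any external
## framework.

.im2col <- function(x, w) {
  L <- ncol(x)
  P <- L - w + 1L
  out <- matrix(0, 4L * w, P)
  for (j in seq_len(w))
    out[(4L * (j - 1L) + 1L):(4L * j), ] <- x[, j:(j + P - 1L), drop = FALSE]
  out
}

## pooling windows over P conv positions; p$pool = Inf gives global pooling
.pool_windows <- function(P, pool) {
  if (is.null(pool) || !is.finite(pool) || pool >= P) return(list(seq_len(P)))
  starts <- seq.int(1L, P, by = pool)
  lapply(starts, function(s) s:min(s + pool - 1L, P))
}

## forward pass over a list of 4 x L matrices (equal L within the batch)
.cnn_forward <- function(p, xs) {
  B <- length(xs)
  nf <- nrow(p$Wc)
  w <- p$w
  L <- ncol(xs[[1L]])
  if (L < w) .contract_error("input length ", L, " shorter than filter width ", w)
  P <- L - w + 1L
  wins <- .pool_windows(P, p$pool)
  nw <- length(wins)
  if (ncol(p$Wh) != nf * nw)
    .contract_error("dense layer expects ", ncol(p$Wh), " pooled features; ",
      "input of length ", L, " yields ", nf * nw)
  Xc <- matrix(0, 4L * w, P * B)
  for (i in seq_len(B)) {
    if (ncol(xs[[i]]) != L) .contract_error("batch inputs must share one length")
    Xc[, ((i - 1L) * P + 1L):(i * P)] <- .im2col(xs[[i]], w)
  }
  Z <- p$Wc %*% Xc + p$bc
  A <- Z * (Z > 0)
  H <- matrix(0, nf * nw, B)
  amax <- matrix(0L, nf * nw, B)   # absolute conv position of each window max
  for (i in seq_len(B)) {
    blk <- A[, ((i - 1L) * P + 1L):(i * P), drop = FALSE]
    for (j in seq_len(nw)) {
      sub <- blk[, wins[[j]], drop = FALSE]
      am <- max.col(sub, ties.method = "first")
      rows <- ((j - 1L) * nf + 1L):(j * nf)
      H[rows, i] <- sub[cbind(seq_len(nf), am)]
      amax[rows, i] <- wins[[j]][am]
    }
  }
  Zh <- p$Wh %*% H + p$bh
  Hh <- Zh * (Zh > 0)
  Y <- p$Wo %*% Hh + p$bo
  list(Y = Y, Xc = Xc, Z = Z, H = H, Zh = Zh, Hh = Hh, amax = amax,
    P = P, B = B, L = L, nw = nw)
}

## scatter pooled-feature gradients back onto conv activations for one
## sequence: dH column (nf*nw) -> dA (nf x P)
.cnn_unpool <- function(dHcol, amaxcol, nf, nw, P) {
  dA <- matrix(0, nf, P)
  for (j in seq_len(nw)) {
    rows <- ((j - 1L) * nf + 1L):(j * nf)
    idx <- cbind(seq_len(nf), amaxcol[rows])
    dA[idx] <- dA[idx] + dHcol[rows]
  }
  dA
}

## dY[task]/dX for every input in the batch
.cnn_input_grad <- function(p, xs, task) {
  f <- .cnn_forward(p, xs)
  nf <- nrow(p$Wc)
  dHh <- matrix(p$Wo[task, ], nrow = length(p$bh), ncol = f$B)
  dZh <- dHh * (f$Zh > 0)
  dH <- crossprod(p$Wh, dZh)
  grads <- vector("list", f$B)
  for (i in seq_len(f$B)) {
    cols <- ((i - 1L) * f$P + 1L):(i * f$P)
    dA <- .cnn_unpool(dH[, i], f$amax[, i], nf, f$nw, f$P)
    dZ <- dA * (f$Z[, cols, drop = FALSE] > 0)
    dXc <- crossprod(p$Wc, dZ)
    G <- matrix(0, 4L, f$L, dimnames = list(.BASES, NULL))
    for (j in seq_len(p$w)) {
      idx <- j:(j + f$P - 1L)
      G[, idx] <- G[, idx] + dXc[(4L * (j - 1L) + 1L):(4L * j), , drop = FALSE]
    }
    grads[[i]] <- G
  }
  grads
}

## parameter gradients for binary cross-entropy on logits of one task
.cnn_param_grad <- function(p, xs, labels, task) {
  f <- .cnn_forward(p, xs)
  nf <- nrow(p$Wc)
  y <- f$Y[task, ]
  prob <- 1 / (1 + exp(-y))
  loss <- -mean(labels * log(prob + 1e-12) + (1 - labels) * log(1 - prob + 1e-12))
  dY <- matrix(0, nrow(p$Wo), f$B)
  dY[task, ] <- (prob - labels) / f$B
  dWo <- dY %*% t(f$Hh)
  dbo <- rowSums(dY)
  dHh <- crossprod(p$Wo, dY)
  dZh <- dHh * (f$Zh > 0)
  dWh <- dZh %*% t(f$H)
  dbh <- rowSums(dZh)
  dH <- crossprod(p$Wh, dZh)
  dZ <- matrix(0, nf, f$P * f$B)
  for (i in seq_len(f$B)) {
    cols <- ((i - 1L) * f$P + 1L):(i * f$P)
    dA <- .cnn_unpool(dH[, i], f$amax[, i], nf, f$nw, f$P)
    dZ[, cols] <- dA * (f$Z[, cols, drop = FALSE] > 0)
  }
  dWc <- dZ %*% t(f$Xc)
  dbc <- rowSums(dZ)
  list(loss = loss,
    grads = list(Wc = dWc, bc = dbc, Wh = dWh, bh = dbh, Wo = dWo, bo = dbo))
}

## ---- dense MLP on flattened 4 x L input ----

## X: d x B matrix of flattened inputs
.mlp_forward <- function(p, X) {
  nl <- length(p$W)
  Hs <- vector("list", nl + 1L)
  Zs <- vector("list", nl)
  Hs[[1L]] <- X
  H <- X
  for (k in seq_len(nl)) {
    Z <- p$W[[k]] %*% H + p$b[[k]]
    H <- if (k < nl) Z * (Z > 0) else Z
    Zs[[k]] <- Z
    Hs[[k + 1L]] <- H
  }
  list(Y = H, Zs = Zs, Hs = Hs)
}

.mlp_input_grad <- function(p, X, task) {
  f <- .mlp_forward(p, X)
  nl <- length(p$W)
  dH <- matrix(0, nrow(f$Y), ncol(X))
  dH[task, ] <- 1
  for (k in nl:1) {
    dZ <- if (k < nl) dH * (f$Zs[[k]] > 0) else dH
    dH <- crossprod(p$W[[k]], dZ)
  }
  dH
}

## mean squared error parameter gradients
.mlp_param_grad <- function(p, X, targets, task) {
  f <- .mlp_forward(p, X)
  nl <- length(p$W)
  B <- ncol(X)
  y <- f$Y[task, ]
  resid <- y - targets
  loss <- mean(resid^2)
  dH <- matrix(0, nrow(f$Y), B)
  dH[task, ] <- 2 * resid / B
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  for (k in nl:1) {
    dZ <- if (k < nl) dH * (f$Zs[[k]] > 0) else dH
    gW[[k]] <- dZ %*% t(f$Hs[[k]])
    gb[[k]] <- rowSums(dZ)
    dH <- crossprod(p$W[[k]], dZ)
  }
  list(loss = loss, grads = list(W = gW, b = gb))
}

## ---- Adam over an arbitrary nested list of arrays ----

.zero_like <- function(x) {
  if (is.list(x)) lapply(x, .zero_like) else x * 0
}

.adam_update <- function(p, g, m, v, t, lr) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      r <- .adam_update(p[[i]], g[[i]], m[[i]], v[[i]], t, lr)
      p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- 0.9 * m + 0.1 * g
  v <- 0.999 * v + 0.001 * g * g
  p <- p - lr * (m / (1 - 0.9^t)) / (sqrt(v / (1 - 0.999^t)) + 1e-8)
  list(p = p, m = m, v = v)
}
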