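# Low-level recurrent and fully connected layers with analytic gradients.
# All operations are batched: the leading dimension is the example index.
# Parameters are plain lists of matrices/vectors so they can be flattened to a
# numeric vector for the optimizer and for finite-difference gradient checks.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Initialise one LSTM cell: input dim d, state size s.
# Weight scale 1/sqrt(fan_in); forget-gate bias starts at 1 (standard practice
# so memory is retained early in training).
init_lstm <- function(d, s) {
  b <- rep(0, 4 * s)
  b[s + 1:s] <- 1
  list(Wx = matrix(stats::rnorm(d * 4 * s, sd = 1 / sqrt(d)), d, 4 * s),
       Wh = matrix(stats::rnorm(s * 4 * s, sd = 1 / sqrt(s)), s, 4 * s),
       b = b)
}

init_linear <- function(d_in, d_out) {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = 1 / sqrt(d_in)), d_in, d_out),
       b = rep(0, d_out))
}

# Forward pass of an LSTM over X (n x T x d). H0/C0 are n x s or NULL (zeros).
# Returns final state H plus the caches needed for backprop.
lstm_forward <- function(X, p, H0 = NULL, C0 = NULL) {
  n <- dim(X)[1]; Tn <- dim(X)[2]
  s <- nrow(p$Wh)
  if (is.null(H0)) H0 <- matrix(0, n, s)
  if (is.null(C0)) C0 <- matrix(0, n, s)
  I <- Fg <- G <- O <- Cs <- Th <- Hs <- array(0, c(n, Tn, s))
  H <- H0; C <- C0
  B <- matrix(p$b, n, 4 * s, byrow = TRUE)
  for (t in seq_len(Tn)) {
    x <- matrix(X[, t, ], n)
    a <- x %*% p$Wx + H %*% p$Wh + B
    i <- sigmoid(a[, 1:s, drop = FALSE])
    f <- sigmoid(a[, s + 1:s, drop = FALSE])
    g <- tanh(a[, 2 * s + 1:s, drop = FALSE])
    o <- sigmoid(a[, 3 * s + 1:s, drop = FALSE])
    C <- f * C + i * g
    th <- tanh(C)
    H <- o * th
    I[, t, ] <- i; Fg[, t, ] <- f; G[, t, ] <- g; O[, t, ] <- o
    Cs[, t, ] <- C; Th[, t, ] <- th; Hs[, t, ] <- H
  }
  list(H = H, C = C,
       cache = list(X = X, I = I, Fg = Fg, G = G, O = O, Cs = Cs, Th = Th,
                    Hs = Hs, H0 = H0, C0 = C0, s = s, n = n, Tn = Tn))
}

# Backprop through lstm_forward given the gradient at the final hidden state.
# Only the final state feeds downstream layers, so no per-step dH injection.
lstm_backward <- function(dH, cache, p) {
  s <- cache$s; n <- cache$n; Tn <- cache$Tn
  d <- dim(cache$X)[3]
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  db <- rep(0, length(p$b))
  dX <- array(0, dim(cache$X)[1:3])
  dC <- matrix(0, n, s)
  for (t in rev(seq_len(Tn))) {
    i <- matrix(cache$I[, t, ], n); f <- matrix(cache$Fg[, t, ], n)
    g <- matrix(cache$G[, t, ], n); o <- matrix(cache$O[, t, ], n)
    th <- matrix(cache$Th[, t, ], n)
    c_prev <- if (t == 1) cache$C0 else matrix(cache$Cs[, t - 1, ], n)
    h_prev <- if (t == 1) cache$H0 else matrix(cache$Hs[, t - 1, ], n)
    x <- matrix(cache$X[, t, ], n)
    do <- dH * th
    dC <- dC + dH * o * (1 - th^2)
    di <- dC * g
    dg <- dC * i
    df <- dC * c_prev
    dC <- dC * f
    da <- cbind(di * i * (1 - i), df * f * (1 - f), dg * (1 - g^2), do * o * (1 - o))
    dWx <- dWx + crossprod(x, da)
    dWh <- dWh + crossprod(h_prev, da)
    db <- db + colSums(da)
    dX[, t, ] <- da %*% t(p$Wx)
    dH <- da %*% t(p$Wh)
  }
  list(Wx = dWx, Wh = dWh, b = db, dX = dX, dH0 = dH, dC0 = dC)
}

# Fully connected head: hidden ReLU layers (optional inverted-dropout masks,
# one per hidden layer) followed by a linear output layer.
fc_forward <- function(feat, fc, out, masks = NULL) {
  acts <- list(feat)
  relu_mask <- list()
  A <- feat
  for (l in seq_along(fc)) {
    Z <- A %*% fc[[l]]$W + matrix(fc[[l]]$b, nrow(A), length(fc[[l]]$b), byrow = TRUE)
    R <- Z * (Z > 0)
    relu_mask[[l]] <- Z > 0
    if (!is.null(masks)) R <- R * masks[[l]]
    acts[[l + 1]] <- R
    A <- R
  }
  y <- A %*% out$W + matrix(out$b, nrow(A), length(out$b), byrow = TRUE)
  list(y = y, cache = list(acts = acts, relu_mask = relu_mask, masks = masks))
}

fc_backward <- function(dy, cache, fc, out) {
  acts <- cache$acts
  L <- length(fc)
  g_out <- list(W = crossprod(acts[[L + 1]], dy), b = colSums(dy))
  dA <- dy %*% t(out$W)
  g_fc <- vector("list", L)
  for (l in rev(seq_len(L))) {
    if (!is.null(cache$masks)) dA <- dA * cache$masks[[l]]
    dZ <- dA * cache$relu_mask[[l]]
    g_fc[[l]] <- list(W = crossprod(acts[[l]], dZ), b = colSums(dZ))
    dA <- dZ %*% t(fc[[l]]$W)
  }
  list(fc = g_fc, out = g_out, dfeat = dA)
}

# flatten a nested parameter list to a numeric vector and back
flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(v, skeleton) {
  pos <- 0
  rebuild <- function(x) {
    if (is.list(x)) return(lapply(x, rebuild))
    k <- length(x)
    out <- v[pos + seq_len(k)]
    pos <<- pos + k
    if (is.matrix(x)) dim(out) <- dim(x)
    out
  }
  out <- rebuild(skeleton)
  stopifnot(pos == length(v))
  out
}

# elementwise sum of two parameter lists with identical structure
add_params <- function(a, b) {
  if (is.list(a)) return(mapply(add_params, a, b, SIMPLIFY = FALSE))
  a + b
}
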