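# Minimal convolutional-network engine.
#
# Activations are dense arrays [H, W, C, B] in double precision. Convolutions
# are lowered to one BLAS matrix multiply per batch via im2col; the gather /
# scatter index map depends only on (H, W, k, dilation) and is cached. All
# gradients are written out explicitly, so every training loop in the package
# is plain R with no external autodiff dependency.

.im2col_cache <- new.env(parent = emptyenv())

# Index map for same-padded k x k convolution with dilation d on an H x W
# grid. Returns Mvec: for output pixel p (column-major) and tap t, the linear
# index into the padded (Hp x Wp) plane; plus the sorted unique indices used
# to scatter-accumulate the input gradient.
im2col_index <- function(H, W, k, d) {
  key <- paste(H, W, k, d, sep = "x")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- d * (k - 1) / 2
  stopifnot(p == floor(p))  # odd kernels only
  Hp <- H + 2 * p; Wp <- W + 2 * p
  i <- rep(seq_len(H), times = W)          # output pixel rows, col-major
  j <- rep(seq_len(W), each = H)
  a <- rep(seq_len(k), times = k)          # tap offsets, col-major
  b <- rep(seq_len(k), each = k)
  r <- outer(i, (a - 1L) * d, `+`)         # HW x KK padded row
  cc <- outer(j, (b - 1L) * d, `+`)        # HW x KK padded col
  M <- r + (cc - 1L) * Hp
  out <- list(Mvec = as.vector(M), ug = sort(unique(as.vector(M))),
              Hp = Hp, Wp = Wp, pad = p)
  .im2col_cache[[key]] <- out
  out
}

# Forward pass of a same-padded convolution.
# W: [k, k, Cin, Cout]; b: numeric(Cout); x: [H, W, Cin, B].
# Returns list(out = [H, W, Cout, B], X = im2col matrix kept for backward).
conv_fwd <- function(W, b, x, dilation = 1L) {
  dW <- dim(W); k <- dW[1]; cin <- dW[3]; cout <- dW[4]
  dx <- dim(x); H <- dx[1]; Wd <- dx[2]; B <- dx[4]
  if (dx[3] != cin) {
    stop_validation("conv: input has %d channels, weights expect %d", dx[3], cin)
  }
  ix <- im2col_index(H, Wd, k, dilation)
  HW <- H * Wd; KK <- k * k
  padded <- array(0, c(ix$Hp, ix$Wp, cin, B))
  padded[(ix$pad + 1):(ix$pad + H), (ix$pad + 1):(ix$pad + Wd), , ] <- x
  dim(padded) <- c(ix$Hp * ix$Wp, cin, B)
  X <- matrix(0, HW * B, KK * cin)
  for (bi in seq_len(B)) {
    Xb <- padded[, , bi, drop = FALSE]
    dim(Xb) <- c(ix$Hp * ix$Wp, cin)
    Xb <- Xb[ix$Mvec, , drop = FALSE]      # (HW*KK) x Cin, pixel-fastest
    dim(Xb) <- c(HW, KK * cin)
    X[((bi - 1) * HW + 1):(bi * HW), ] <- Xb
  }
  W2 <- W; dim(W2) <- c(KK * cin, cout)
  Y <- X %*% W2
  Y <- Y + matrix(b, nrow(Y), cout, byrow = TRUE)
  out <- aperm(array(Y, c(H, Wd, B, cout)), c(1, 2, 4, 3))
  list(out = out, X = X, dims = c(H = H, W = Wd, B = B), k = k,
       dilation = dilation)
}

# Backward pass. dout: [H, W, Cout, B]. Returns grads for W, b, and input.
conv_bwd <- function(W, cache, dout) {
  dWm <- dim(W); k <- dWm[1]; cin <- dWm[3]; cout <- dWm[4]
  H <- cache$dims[["H"]]; Wd <- cache$dims[["W"]]; B <- cache$dims[["B"]]
  ix <- im2col_index(H, Wd, k, cache$dilation)
  HW <- H * Wd; KK <- k * k
  dY <- matrix(aperm(dout, c(1, 2, 4, 3)), HW * B, cout)
  dW2 <- crossprod(cache$X, dY)
  db <- colSums(dY)
  W2 <- W; dim(W2) <- c(KK * cin, cout)
  dX <- tcrossprod(dY, W2)                 # (HW*B) x (KK*Cin)
  dx <- array(0, c(H, Wd, cin, B))
  dpad <- matrix(0, ix$Hp * ix$Wp, cin)
  for (bi in seq_len(B)) {
    dXb <- dX[((bi - 1) * HW + 1):(bi * HW), , drop = FALSE]
    dim(dXb) <- c(HW * KK, cin)
    dpad[] <- 0
    dpad[ix$ug, ] <- rowsum(dXb, ix$Mvec)
    dpb <- array(dpad, c(ix$Hp, ix$Wp, cin))
    dx[, , , bi] <- dpb[(ix$pad + 1):(ix$pad + H),
                        (ix$pad + 1):(ix$pad + Wd), , drop = FALSE]
  }
  dim(dW2) <- c(k, k, cin, cout)
  list(dW = dW2, db = db, dx = dx)
}

relu_fwd <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, mask = mask)
}

relu_bwd <- function(cache, dout) {
  dout[!cache$mask] <- 0
  dout
}

# He-style weight init for a [k, k, cin, cout] kernel.
init_conv <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * cin))
  list(W = array(stats::rnorm(k * k * cin * cout, sd = sd), c(k, k, cin, cout)),
       b = numeric(cout))
}

zeros_like <- function(par) lapply(par, function(p) array(0, dim(p) %||% length(p)))

#' @noRd
opt_sgd_init <- function(par) list(v = zeros_like(par))

# SGD with momentum over a flat named list of parameter arrays.
opt_sgd_step <- function(par, grads, state, lr, momentum = 0.9) {
  for (nm in names(par)) {
    state$v[[nm]] <- momentum * state$v[[nm]] - lr * grads[[nm]]
    par[[nm]] <- par[[nm]] + state$v[[nm]]
  }
  list(par = par, state = state)
}

#' @noRd
opt_adamw_init <- function(par) list(m = zeros_like(par), v = zeros_like(par), t = 0L)

opt_adamw_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8, weight_decay = 0.0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    par[[nm]] <- par[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                     weight_decay * par[[nm]])
  }
  list(par = par, state = state)
}

# Add grad b into accumulator a (same named structure), a may have NULL slots.
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

# Extract image 1 from an [H, W, C, 1] batch without dropping the channel
# dimension even when C = 1.
drop_batch <- function(a) {
  d <- dim(a)
  out <- a[, , , 1, drop = FALSE]
  dim(out) <- d[1:3]
  out
}

# Stack a list of [H, W, C] grids into one [H, W, C, B] batch array.
stack_grids <- function(grids) {
  d <- dim(grids[[1]])
  out <- array(0, c(d, length(grids)))
  for (i in seq_along(grids)) out[, , , i] <- grids[[i]]
  out
}
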