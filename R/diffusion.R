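# Unconditional DDPM: noise schedule, forward process, training objective,
# ancestral sampling and replay-set generation.

#' Build a linear noise schedule
#'
#' Constructs the `beta / alpha / alpha-bar / sigma` arrays that govern the
#' forward and reverse diffusion processes. Betas are linearly spaced from
#' `beta_start` to `beta_end`; `alpha_s = 1 - beta_s`;
#' `alpha_bar_s = prod(alpha_1..alpha_s)`. The reverse-step standard deviation
#' defaults to `sigma_s^2 = beta_s`, with `sigma_1` forced to zero so that the
#' final reverse step is deterministic.
#'
#' @param S total number of diffusion steps (positive integer).
#' @param beta_start,beta_end endpoints of the linear beta ramp; must satisfy
#'   `0 < beta_start <= beta_end < 1`. Defaults follow the original DDPM
#'   convention (1e-4 to 0.02).
#' @return an object of class `noise_schedule` with fields `S`, `betas`,
#'   `alphas`, `alpha_bars`, `sigmas`.
#' @export
#' @examples
#' sched <- build_linear_schedule(10)
#' sched$alpha_bars
build_linear_schedule <- function(S, beta_start = 1e-4, beta_end = 0.02) {
  if (!is.numeric(S) || length(S) != 1 || S < 1 || S != floor(S)) {
    stop_validation("S must be a positive integer, got %s", format(S))
  }
  if (!(beta_start > 0 && beta_end < 1 && beta_start <= beta_end)) {
    stop_validation("need 0 < beta_start <= beta_end < 1 (got %g, %g)",
                    beta_start, beta_end)
  }
  betas <- if (S == 1) beta_start else seq(beta_start, beta_end, length.out = S)
  alphas <- 1 - betas
  alpha_bars <- cumprod(alphas)
  sigmas <- sqrt(betas)
  sigmas[1] <- 0  # z = 0 at s = 1: last reverse step is noiseless
  structure(list(S = as.integer(S), betas = betas, alphas = alphas,
                 alpha_bars = alpha_bars, sigmas = sigmas),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule> S = %d, beta in [%g, %g], alpha_bar_S = %g\n",
              x$S, x$betas[1], x$betas[x$S], x$alpha_bars[x$S]))
  invisible(x)
}

check_step <- function(s, sched) {
  if (!is.numeric(s) || length(s) != 1 || s != floor(s) || s < 1 || s > sched$S) {
    stop(sprintf("diffusion step s = %s out of range 1..%d", format(s), sched$S),
         call. = FALSE)
  }
  as.integer(s)
}

#' Forward diffusion: noise a clean image to step s
#'
#' Computes `sqrt(alpha_bar_s) * x0 + sqrt(1 - alpha_bar_s) * eps`, the closed
#' form of the forward process at step `s`.
#'
#' @param x0 clean image grid, array `[H, W, C]` with values in `[-1, 1]`.
#' @param s diffusion step in `1..S`.
#' @param eps noise grid, same shape as `x0` (standard normal draws during
#'   training).
#' @param sched a [build_linear_schedule()] schedule.
#' @return the noised grid, same shape as `x0`.
#' @export
forward_noise <- function(x0, s, eps, sched) {
  s <- check_step(s, sched)
  if (!identical(dim(x0), dim(eps))) {
    stop_validation("x0 and eps shapes differ: [%s] vs [%s]",
                    paste(dim(x0), collapse = ","),
                    paste(dim(eps), collapse = ","))
  }
  ab <- sched$alpha_bars[s]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' DDPM training objective at one (image, step, noise) triple
#'
#' Mean squared discrepancy between the injected noise and the model's
#' prediction on the noised input. The squared norm is reduced as the mean
#' over elements so the value is invariant to image size.
#'
#' @param model a noise predictor: either a fitted [fit_diffusion()] network
#'   or any function `(x, s) -> array` of matching shape.
#' @inheritParams forward_noise
#' @return a nonnegative scalar.
#' @export
ddpm_training_loss <- function(model, x0, s, eps, sched) {
  xs <- forward_noise(x0, s, eps, sched)
  pred <- predict_noise(model, xs, s)
  if (!identical(dim(pred), dim(eps))) {
    stop_validation("noise predictor returned shape [%s], expected [%s]",
                    paste(dim(pred), collapse = ","),
                    paste(dim(eps), collapse = ","))
  }
  mean((eps - pred)^2)
}

#' One ancestral (reverse) diffusion step
#'
#' `x_{s-1} = (x_s - (1 - alpha_s) / sqrt(1 - alpha_bar_s) * eps_hat) /
#' sqrt(alpha_s) + sigma_s * z`. At `s = 1` the injected noise `z` must be
#' all-zeros (the final step is deterministic).
#'
#' @param model noise predictor (see [ddpm_training_loss()]).
#' @param x_s current noisy grid.
#' @param s step index in `1..S`.
#' @param sched noise schedule.
#' @param z standard-normal grid of the same shape (or zeros at `s = 1`).
#' @return the denoised grid at step `s - 1`.
#' @export
reverse_step <- function(model, x_s, s, sched, z) {
  s <- check_step(s, sched)
  if (!identical(dim(x_s), dim(z))) {
    stop_validation("x_s and z shapes differ")
  }
  if (s == 1 && any(z != 0)) {
    stop_validation("z must be all-zeros at s = 1")
  }
  eps_hat <- predict_noise(model, x_s, s)
  a <- sched$alphas[s]
  ab <- sched$alpha_bars[s]
  (x_s - (1 - a) / sqrt(1 - ab) * eps_hat) / sqrt(a) + sched$sigmas[s] * z
}

#' Draw one image by ancestral sampling
#'
#' Starts from `x_S ~ N(0, I)` and applies [reverse_step()] from `s = S` down
#' to 1. Fully deterministic for a given `rng_seed`.
#'
#' @param model noise predictor.
#' @param sched noise schedule; if `model` is a fitted network its step count
#'   must equal `sched$S`.
#' @param shape integer vector `c(H, W, C)`.
#' @param rng_seed integer seed for the trajectory's noise draws.
#' @return an `[H, W, C]` grid (unbounded; callers clip to `[-1, 1]` when
#'   exporting images).
#' @export
ancestral_sample <- function(model, sched, shape, rng_seed) {
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (inherits(model, "noise_net") && model$S != sched$S) {
    stop_validation("model was built for S = %d but schedule has S = %d",
                    model$S, sched$S)
  }
  with_seed(rng_seed, {
    x <- array(stats::rnorm(prod(shape)), shape)
    for (s in seq(sched$S, 1L)) {
      z <- if (s > 1) array(stats::rnorm(prod(shape)), shape) else
        array(0, shape)
      x <- reverse_step(model, x, s, sched, z)
    }
    x
  })
}

# ---- noise-predictor network -----------------------------------------------

# Sinusoidal embedding of the step index, dimension emb_dim (even).
step_embedding <- function(s, emb_dim) {
  half <- emb_dim %/% 2
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / half)
  c(sin(s * freqs), cos(s * freqs))
}

#' Create an untrained noise-predictor network
#'
#' A small fully-convolutional denoiser: a 3x3 encoder convolution whose
#' output receives a per-channel bias from a sinusoidal step embedding, a
#' dilated 3x3 context convolution, and a 3x3 projection back to image
#' channels. Sized for desk-scale (32x32) experiments.
#'
#' @param channels image channels.
#' @param width hidden feature channels.
#' @param emb_dim step-embedding dimension (even).
#' @param S number of diffusion steps the model is trained for.
#' @param seed RNG seed for weight initialization.
#' @return an object of class `noise_net`.
#' @export
new_noise_net <- function(channels = 3L, width = 16L, emb_dim = 16L, S = 50L,
                          seed = 1L) {
  stopifnot(emb_dim %% 2 == 0)
  par <- with_seed(seed, {
    c1 <- init_conv(3, channels, width)
    c2 <- init_conv(3, width, width)
    c3 <- init_conv(3, width, channels)
    list(c1.W = c1$W, c1.b = c1$b,
         emb.W = matrix(stats::rnorm(emb_dim * width, sd = 1 / sqrt(emb_dim)),
                        emb_dim, width),
         c2.W = c2$W, c2.b = c2$b,
         c3.W = c3$W, c3.b = c3$b)
  })
  structure(list(par = par, channels = as.integer(channels),
                 width = as.integer(width), emb_dim = as.integer(emb_dim),
                 S = as.integer(S), loss_trace = numeric(0)),
            class = "noise_net")
}

#' @export
print.noise_net <- function(x, ...) {
  cat(sprintf("<noise_net> %d-channel, width %d, S = %d, %s\n",
              x$channels, x$width, x$S,
              if (length(x$loss_trace)) sprintf("trained %d epochs (final loss %.4f)",
                                                length(x$loss_trace),
                                                x$loss_trace[length(x$loss_trace)])
              else "untrained"))
  invisible(x)
}

# Batched forward pass. x: [H, W, C, B]; steps: integer vector length B.
noise_net_fwd <- function(net, x, steps) {
  B <- dim(x)[4]
  stopifnot(length(steps) == B)
  p <- net$par
  f1 <- conv_fwd(p$c1.W, p$c1.b, x, 1L)
  emb <- vapply(steps, step_embedding, numeric(net$emb_dim),
                emb_dim = net$emb_dim)          # emb_dim x B
  bias <- crossprod(emb, p$emb.W)               # B x width
  h1 <- f1$out
  for (bi in seq_len(B)) {
    h1[, , , bi] <- h1[, , , bi] +
      rep(bias[bi, ], each = dim(x)[1] * dim(x)[2])
  }
  r1 <- relu_fwd(h1)
  f2 <- conv_fwd(p$c2.W, p$c2.b, r1$out, 2L)
  r2 <- relu_fwd(f2$out)
  f3 <- conv_fwd(p$c3.W, p$c3.b, r2$out, 1L)
  list(out = f3$out, f1 = f1, r1 = r1, f2 = f2, r2 = r2, f3 = f3, emb = emb)
}

noise_net_bwd <- function(net, cache, dout) {
  p <- net$par
  g3 <- conv_bwd(p$c3.W, cache$f3, dout)
  d2 <- relu_bwd(cache$r2, g3$dx)
  g2 <- conv_bwd(p$c2.W, cache$f2, d2)
  d1 <- relu_bwd(cache$r1, g2$dx)
  # the step-embedding bias is added per (channel, image): its gradient is the
  # spatial sum of d1
  dbias <- apply(d1, c(3, 4), sum)              # width x B
  demb.W <- tcrossprod(cache$emb, dbias)        # emb_dim x width
  g1 <- conv_bwd(p$c1.W, cache$f1, d1)
  list(c1.W = g1$dW, c1.b = g1$db, emb.W = demb.W,
       c2.W = g2$dW, c2.b = g2$db, c3.W = g3$dW, c3.b = g3$db)
}

#' Predict the injected noise for a (noisy image, step) pair
#'
#' Generic over predictor representations: fitted `noise_net` objects and
#' plain functions `(x, s) -> array` (useful for analytic oracles in tests).
#'
#' @param model predictor.
#' @param x `[H, W, C]` grid.
#' @param s step index.
#' @return predicted noise grid of the same shape.
#' @export
predict_noise <- function(model, x, s) UseMethod("predict_noise")

#' @export
predict_noise.function <- function(model, x, s) model(x, s)

#' @export
predict_noise.noise_net <- function(model, x, s) {
  check_grid(x, 3, "image")
  x4 <- array(x, c(dim(x), 1L))
  drop_batch(noise_net_fwd(model, x4, s)$out)
}

#' Train the diffusion noise predictor
#'
#' Minimizes the DDPM objective over a dataset of clean images: each epoch
#' visits every image once in a shuffled order, draws a uniform step and
#' standard-normal noise per image, and takes one AdamW step per mini-batch on
#' the mean squared noise-prediction error. The per-epoch mean loss is
#' recorded in the returned network's `loss_trace`.
#'
#' @param images list of `[H, W, C]` grids in `[-1, 1]`.
#' @param sched noise schedule.
#' @param epochs number of passes over the data (>= 1).
#' @param batch_size mini-batch size.
#' @param lr AdamW learning rate.
#' @param width,emb_dim network size (see [new_noise_net()]).
#' @param seed master seed for init, shuffling and noise draws.
#' @return a trained `noise_net` with `$loss_trace`.
#' @export
fit_diffusion <- function(images, sched, epochs = 20L, batch_size = 16L,
                          lr = 1e-3, width = 16L, emb_dim = 16L, seed = 1L) {
  if (length(images) == 0) stop_validation("empty image dataset")
  if (epochs < 1) stop_validation("epochs must be >= 1, got %s", format(epochs))
  shp <- dim(images[[1]])
  net <- new_noise_net(channels = shp[3], width = width, emb_dim = emb_dim,
                       S = sched$S, seed = derive_seed(seed, "diffusion", "init"))
  state <- opt_adamw_init(net$par)
  n <- length(images)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ep_losses <- with_seed(derive_seed(seed, "diffusion", "epoch", ep), {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        B <- length(idx)
        x0 <- stack_grids(images[idx])
        steps <- sample.int(sched$S, B, replace = TRUE)
        eps <- array(stats::rnorm(prod(shp) * B), c(shp, B))
        ab <- sched$alpha_bars[steps]
        xs <- x0
        for (bi in seq_len(B)) {
          xs[, , , bi] <- sqrt(ab[bi]) * x0[, , , bi] +
            sqrt(1 - ab[bi]) * eps[, , , bi]
        }
        fwd <- noise_net_fwd(net, xs, steps)
        resid <- fwd$out - eps
        loss <- mean(resid^2)
        grads <- noise_net_bwd(net, fwd, 2 * resid / length(resid))
        upd <- opt_adamw_step(net$par, grads, state, lr = lr)
        net$par <- upd$par
        state <- upd$state
        losses <- c(losses, loss)
      }
      losses
    })
    trace[ep] <- mean(ep_losses)
    sr_log("info", sprintf("diffusion epoch %d/%d mean loss %.5f",
                           ep, epochs, trace[ep]))
  }
  net$loss_trace <- trace
  net
}

#' Generate a replay set of synthetic images
#'
#' Draws `N` ancestral samples from a trained (frozen) diffusion model, each
#' with a seed derived from one master seed, and records provenance
#' (checkpoint id, master seed, schedule length).
#'
#' @param model trained noise predictor.
#' @param sched noise schedule.
#' @param N number of images (>= 1).
#' @param shape `c(H, W, C)`.
#' @param rng_seed master seed; image i uses `derive_seed(rng_seed, "replay", i)`.
#' @param ckpt_id optional identifier stored in provenance.
#' @return an object of class `replay_set`: `$images` (list of grids, clipped
#'   to `[-1, 1]`), `$provenance`.
#' @export
generate_replay_set <- function(model, sched, N, shape, rng_seed,
                                ckpt_id = "unnamed") {
  if (!is.numeric(N) || length(N) != 1 || N < 1 || N != floor(N)) {
    stop_validation("N must be a positive integer")
  }
  images <- vector("list", N)
  for (i in seq_len(N)) {
    x <- ancestral_sample(model, sched, shape,
                          derive_seed(rng_seed, "replay", i))
    images[[i]] <- pmin(pmax(x, -1), 1)
  }
  structure(list(images = images,
                 provenance = list(ckpt_id = ckpt_id, seed = rng_seed,
                                   S = sched$S, N = as.integer(N))),
            class = "replay_set")
}

#' @export
print.replay_set <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<replay_set> %d images of %dx%dx%d (S = %d, seed %d)\n",
              length(x$images), d[1], d[2], d[3],
              x$provenance$S, x$provenance$seed))
  invisible(x)
}
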