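# Unconditional DDPM: schedule algebra, forward/reverse processes, training
# objective, sampling and replay generation.

test_that("linear schedule matches closed forms and validates inputs", {
  # constant beta: alpha_bar_s = (1 - beta)^s
  s3 <- build_linear_schedule(3, 0.1, 0.1)
  expect_equal(s3$alpha_bars, c(0.9, 0.81, 0.729))
  # two-term product
  s2 <- build_linear_schedule(2, 1e-4, 0.02)
  expect_equal(s2$betas, c(1e-4, 0.02))
  expect_equal(s2$alpha_bars, c(0.9999, 0.9999 * 0.98))
  # single step
  s1 <- build_linear_schedule(1, 0.3, 0.3)
  expect_equal(s1$alpha_bars, 1 - 0.3)
  expect_equal(s1$sigmas, 0)  # the last reverse step is always noiseless

  expect_error(build_linear_schedule(0), "positive integer")
  expect_error(build_linear_schedule(5, 0, 0.02), "beta")
  expect_error(build_linear_schedule(5, 0.5, 0.2), "beta")
})

test_that("schedule invariants hold across sizes", {
  for (S in c(1, 2, 10, 100)) {
    sch <- build_linear_schedule(S)
    expect_true(all(sch$betas > 0 & sch$betas < 1))
    expect_equal(sch$alphas, 1 - sch$betas)
    expect_true(all(diff(sch$alpha_bars) < 0) || S == 1)
    expect_true(sch$alpha_bars[S] > 0 && sch$alpha_bars[1] < 1)
    expect_true(all(sch$sigmas >= 0))
    # signal/noise coefficients lie on the unit circle
    expect_equal(sqrt(sch$alpha_bars)^2 + sqrt(1 - sch$alpha_bars)^2,
                 rep(1, S), tolerance = 1e-12)
  }
})

test_that("forward_noise computes sqrt(ab) x0 + sqrt(1-ab) eps", {
  sch <- build_linear_schedule(3, 0.1, 0.1)  # alpha_bar_2 = 0.81
  x0 <- array(1, c(2, 2, 1))
  zeros <- array(0, c(2, 2, 1))
  expect_equal(forward_noise(x0, 2, zeros, sch), sqrt(0.81) * x0)
  eps <- array(-1, c(2, 2, 1))
  expect_equal(forward_noise(x0, 2, eps, sch)[1, 1, 1],
               0.9 - sqrt(0.19), tolerance = 1e-12)
  expect_error(forward_noise(x0, 4, zeros, sch), "out of range")
  expect_error(forward_noise(x0, 2, array(0, c(2, 3, 1)), sch), "differ")
})

test_that("forward_noise preserves unit variance (Monte Carlo)", {
  sch <- build_linear_schedule(20)
  n <- 2e4
  set.seed(11)
  x0 <- array(rnorm(n), c(n, 1, 1))
  eps <- array(rnorm(n), c(n, 1, 1))
  v <- var(as.vector(forward_noise(x0, 13, eps, sch)))
  # Var = 1 exactly; allow 3 standard errors of the variance estimate
  expect_lt(abs(v - 1), 3 * sqrt(2 / n))
})

test_that("ddpm_training_loss: oracle stub is 0, unit residual is 1", {
  sch <- build_linear_schedule(5)
  x0 <- array(runif(12, -1, 1), c(2, 2, 3))
  eps <- array(rnorm(12), c(2, 2, 3))
  oracle <- function(x, s) eps
  expect_equal(ddpm_training_loss(oracle, x0, 3, eps, sch), 0)
  zero_model <- function(x, s) array(0, dim(x))
  ones <- array(1, c(2, 2, 3))
  expect_equal(ddpm_training_loss(zero_model, x0, 3, ones, sch), 1)
  # any non-oracle stub has strictly positive loss on nonzero eps
  expect_gt(ddpm_training_loss(zero_model, x0, 3, eps, sch), 0)
})

test_that("ddpm_training_loss is invariant to joint pixel permutation", {
  sch <- build_linear_schedule(5)
  set.seed(3)
  x0 <- array(runif(16, -1, 1), c(4, 4, 1))
  eps <- array(rnorm(16), c(4, 4, 1))
  const_pred <- array(rnorm(16), c(4, 4, 1))
  perm <- sample(16)
  l1 <- ddpm_training_loss(function(x, s) const_pred, x0, 2, eps, sch)
  l2 <- ddpm_training_loss(function(x, s) array(const_pred[perm], c(4, 4, 1)),
                           array(x0[perm], c(4, 4, 1)), 2,
                           array(eps[perm], c(4, 4, 1)), sch)
  expect_equal(l1, l2)
})

test_that("reverse_step follows the ancestral update exactly", {
  sch <- build_linear_schedule(1, 0.01, 0.01)  # alpha_1 = 0.99
  x1 <- array(1, c(1, 1, 1))
  z0 <- array(0, c(1, 1, 1))
  out <- reverse_step(function(x, s) array(0, dim(x)), x1, 1, sch, z0)
  expect_equal(out[1, 1, 1], 1 / sqrt(0.99), tolerance = 1e-12)
  # nonzero z at s = 1 is rejected
  expect_error(reverse_step(function(x, s) array(0, dim(x)), x1, 1, sch,
                            array(1, c(1, 1, 1))), "all-zeros")
})

test_that("reverse_step with the exact forward noise recovers x0 at S = 1", {
  # at S = 1 the posterior-mean path is exact: with eps_hat = eps,
  # (x_1 - (1-a)/sqrt(1-abar) eps)/sqrt(a) = x0 since abar_1 = a_1
  sch <- build_linear_schedule(1, 0.2, 0.2)
  x0 <- array(0.37, c(1, 1, 1))
  eps <- array(1.3, c(1, 1, 1))
  x1 <- forward_noise(x0, 1, eps, sch)
  rec <- reverse_step(function(x, s) eps, x1, 1, sch, array(0, c(1, 1, 1)))
  expect_equal(rec, x0, tolerance = 1e-12)
})

test_that("reverse_step output is independent of z when sigma is 0", {
  sch <- build_linear_schedule(3)
  sch$sigmas[] <- 0
  x <- array(rnorm(8), c(2, 2, 2))
  m <- function(x, s) array(0.1, dim(x))
  o1 <- reverse_step(m, x, 2, sch, array(rnorm(8), c(2, 2, 2)))
  o2 <- reverse_step(m, x, 2, sch, array(rnorm(8), c(2, 2, 2)))
  expect_equal(o1, o2)
})

test_that("ancestral sampling is deterministic and has the S=1 closed form", {
  sch <- build_linear_schedule(5)
  m <- function(x, s) array(0, dim(x))
  a <- ancestral_sample(m, sch, c(4, 4, 1), rng_seed = 99)
  b <- ancestral_sample(m, sch, c(4, 4, 1), rng_seed = 99)
  expect_identical(a, b)
  # S = 1, zero predictor: output = x_1 / sqrt(alpha_1) for the seeded draw
  sch1 <- build_linear_schedule(1, 0.04, 0.04)
  out <- ancestral_sample(m, sch1, c(3, 3, 1), rng_seed = 5)
  set.seed(5)
  x1 <- array(rnorm(9), c(3, 3, 1))
  expect_equal(out, x1 / sqrt(0.96), tolerance = 1e-12)
})

test_that("Gaussian-oracle ancestral samples match N(0,1) moments", {
  # For x0 ~ N(0, I) the posterior-expected noise is eps*(x, s) =
  # sqrt(1 - alpha_bar_s) * x; under this oracle each reverse step is
  # x <- sqrt(alpha_s) x + sigma_s z, whose stationary variance is 1.
  sch <- build_linear_schedule(50)
  oracle <- function(x, s) sqrt(1 - sch$alpha_bars[s]) * x
  vals <- numeric(0)
  for (i in 1:300) {
    vals <- c(vals, as.vector(ancestral_sample(oracle, sch, c(8, 8, 1),
                                               rng_seed = 1000 + i)))
  }
  expect_lt(abs(mean(vals)), 0.05)
  expect_true(var(vals) > 0.85 && var(vals) < 1.15)
})

test_that("fit_diffusion learns, is deterministic, and validates inputs", {
  set.seed(21)
  # tiny two-blob images: dark background, one bright square, one mid square
  imgs <- lapply(1:40, function(i) {
    x <- array(-0.8, c(16, 16, 1))
    r <- sample(3:10, 2)
    x[r[1]:(r[1] + 3), r[1]:(r[1] + 3), 1] <- 0.7
    x[r[2]:(r[2] + 2), 14 - r[2] + (0:2), 1] <- 0.1
    x
  })
  sch <- build_linear_schedule(10)
  net <- fit_diffusion(imgs, sch, epochs = 6, batch_size = 8, width = 8,
                       seed = 4)
  expect_lt(net$loss_trace[6], net$loss_trace[1])
  net2 <- fit_diffusion(imgs, sch, epochs = 6, batch_size = 8, width = 8,
                        seed = 4)
  expect_identical(net$loss_trace, net2$loss_trace)
  expect_error(fit_diffusion(list(), sch), "empty")
  expect_error(fit_diffusion(imgs, sch, epochs = 0), "epochs")
})

test_that("generate_replay_set: cardinality, determinism, diversity", {
  sch <- build_linear_schedule(8)
  net <- new_noise_net(channels = 1, width = 4, S = 8, seed = 2)
  rs <- generate_replay_set(net, sch, N = 5, c(8, 8, 1), rng_seed = 31)
  expect_length(rs$images, 5)
  expect_true(all(vapply(rs$images, function(x) identical(dim(x), c(8L, 8L, 1L)),
                         logical(1))))
  rs2 <- generate_replay_set(net, sch, N = 5, c(8, 8, 1), rng_seed = 31)
  expect_identical(rs$images, rs2$images)
  # distinct per-image seeds give non-identical images for a non-constant model
  expect_false(identical(rs$images[[1]], rs$images[[2]]))
  expect_equal(rs$provenance$S, 8)
  expect_error(generate_replay_set(net, sch, N = 0, c(8, 8, 1), 1), "positive")
  # model/schedule step-count mismatch
  expect_error(ancestral_sample(net, build_linear_schedule(5), c(8, 8, 1), 1),
               "S = ")
})
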