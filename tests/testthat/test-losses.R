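# Distillation, contrastive and overall losses; pseudo-label merging.

test_that("kd_loss closed forms and validation", {
  expect_equal(kd_loss(list(c(1, 2)), list(c(1, 2)), 1), 0)
  expect_equal(kd_loss(list(c(0, 0)), list(c(3, 4)), 1), 5)   # 3-4-5
  # two layers, weights (1, 2), distances (5, 0.5) -> 6
  expect_equal(kd_loss(list(c(0, 0), 0), list(c(3, 4), 0.5), c(1, 2)), 6)
  # squared variant
  expect_equal(kd_loss(list(c(0, 0)), list(c(3, 4)), 1, squared = TRUE), 25)
  expect_error(kd_loss(list(1), list(1, 2), 1), "lengths")
  expect_error(kd_loss(list(matrix(0, 2, 2)), list(matrix(0, 3, 3)), 1),
               "shapes")
  expect_error(kd_loss(list(1), list(2), c(1, 2)), "layers")
  expect_error(kd_loss(list(1), list(2), -1), "nonnegative")
})

test_that("kd_loss is zero at the fixed point and linear in each omega", {
  set.seed(4)
  A <- list(e1 = array(rnorm(8), c(2, 2, 2)), e2 = rnorm(5))
  B <- list(e1 = array(rnorm(8), c(2, 2, 2)), e2 = rnorm(5))
  for (om in list(c(0.5, 2), c(3, 0), c(1, 1))) {
    expect_equal(kd_loss(A, A, om), 0)
    expect_equal(kd_loss(A, B, 2 * om), 2 * kd_loss(A, B, om))
  }
  # additivity across layers at unit weights
  expect_equal(kd_loss(A, B, c(1, 0)) + kd_loss(A, B, c(0, 1)),
               kd_loss(A, B, c(1, 1)))
})

test_that("projection head returns deterministic unit vectors", {
  head <- new_projection_head(6, 16, 8, seed = 9)
  z <- rfeat(6, 1)
  p1 <- project(head, z)
  expect_equal(sqrt(sum(p1^2)), 1, tolerance = 1e-6)
  expect_identical(p1, project(head, z))
  expect_length(p1, 8)
  z2 <- rfeat(6, 2)
  expect_false(identical(p1, project(head, z2)))
  expect_error(project(head, rnorm(5)), "length")
})

test_that("contrastive_loss closed forms", {
  head <- new_projection_head(4, 8, 8, seed = 2)
  z <- rfeat(4, 3)
  # identical features: all three similarities equal -> -log(1/3) = ln 3
  b <- feature_bundle(z, z, z, z, tau = 1)
  expect_equal(contrastive_loss(b, head), log(3), tolerance = 1e-9)
  expect_error(feature_bundle(z, z, z, z, tau = 0), "positive")
  expect_error(feature_bundle(z, z, rnorm(3), z), "dimension")
})

test_that("contrastive loss matches an independent scalar evaluation", {
  # bypass the head: use an identity-like evaluation on raw similarities via
  # a hand-computed softmax for tau = 0.5, pos 0.9, negs 0.1 and -0.2
  pos <- 0.9; n1 <- 0.1; n2 <- -0.2; tau <- 0.5
  expected <- -log(exp(pos / tau) /
                     (exp(pos / tau) + exp(n1 / tau) + exp(n2 / tau)))
  expect_equal(expected, -log(exp(1.8) / (exp(1.8) + exp(0.2) + exp(-0.4))))
  # the package computes the same value once projections give these cosines;
  # verify the softmax core on random projected bundles against plain R
  head <- new_projection_head(5, 8, 6, seed = 12)
  set.seed(30)
  for (i in 1:8) {
    zs <- lapply(1:4, function(j) rnorm(5))
    tau_i <- runif(1, 0.05, 1)
    bl <- feature_bundle(zs[[1]], zs[[2]], zs[[3]], zs[[4]], tau_i)
    p <- lapply(zs, function(z) project(head, z))
    sims <- c(sum(p[[1]] * p[[2]]), sum(p[[1]] * p[[3]]),
              sum(p[[1]] * p[[4]])) / tau_i
    oracle <- -log(exp(sims[1]) / sum(exp(sims)))
    expect_equal(contrastive_loss(bl, head), oracle, tolerance = 1e-9)
    expect_gte(contrastive_loss(bl, head), 0)
  }
})

test_that("contrastive loss decreases in the positive similarity", {
  # monotonicity checked on the softmax core with negatives held fixed
  tau <- 0.2
  vals <- vapply(seq(-1, 1, by = 0.25), function(pos) {
    -log(exp(pos / tau) / (exp(pos / tau) + 2 * exp(0.1 / tau)))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("separable limit drives the loss to zero", {
  # perfect positive (cos 1) and strongly negative similarities at small tau
  tau <- 0.05
  loss <- -log(exp(1 / tau) / (exp(1 / tau) + 2 * exp(-1 / tau)))
  expect_lt(loss, 1e-10)
})

test_that("pseudo_label_merge: threshold, precedence, generated images", {
  reg <- class_registry(list(1:2, 3))
  # unconfident previous model: uniform logits over 3 channels (conf 1/3)
  H <- 4; W <- 4
  unconf <- structure(list(logits = array(0, c(H, W, 3))), class = "seg_outputs")
  gt_mask <- matrix(0, H, W); gt_mask[1, 1:3] <- 1
  gt <- annotated_image(array(0, c(H, W, 3)), 3, gt_mask)
  lab <- pseudo_label_merge(unconf, gt, threshold = 0.7, registry = reg)
  expect_equal(sum(lab == 3), 3)
  expect_equal(sum(lab == 255), 13)
  # confident old-class prediction loses to ground truth inside the mask
  conf <- array(0, c(H, W, 3)); conf[, , 2] <- 25    # class 1 everywhere
  lab2 <- pseudo_label_merge(structure(list(logits = conf), class = "seg_outputs"),
                             gt, threshold = 0.7, registry = reg)
  expect_true(all(lab2[gt_mask == 1] == 3))
  expect_true(all(lab2[gt_mask == 0] == 1))
  # generated image (gt = NULL), confident background -> all background
  bg <- array(0, c(H, W, 3)); bg[, , 1] <- 25
  lab3 <- pseudo_label_merge(structure(list(logits = bg), class = "seg_outputs"),
                             NULL, threshold = 0.7, registry = reg)
  expect_true(all(lab3 == 0))
  expect_error(pseudo_label_merge(unconf, gt, threshold = 1, registry = reg),
               "threshold")
})

test_that("ground truth always wins inside the mask (random cases)", {
  reg <- class_registry(list(1:3, 4))
  set.seed(14)
  for (i in 1:10) {
    logits <- array(rnorm(8 * 8 * 4, sd = 5), c(8, 8, 4))
    mask <- matrix(rbinom(64, 1, 0.3), 8)
    if (sum(mask) == 0) mask[3, 3] <- 1
    gt <- annotated_image(array(0, c(8, 8, 3)), 4, mask)
    lab <- pseudo_label_merge(structure(list(logits = logits),
                                        class = "seg_outputs"),
                              gt, threshold = 0.7, registry = reg)
    expect_true(all(lab[mask == 1] == 4))
  }
})

test_that("overall_loss applies the initial-phase rule and validates", {
  expect_equal(overall_loss(2.0, 17, 99, t = 0), 2.0)
  expect_equal(overall_loss(1, 2, 3, t = 1), 6)
  expect_equal(overall_loss(0, 0, 0, t = 1), 0)
  expect_equal(overall_loss(1, 2, 3, t = 2, multipliers = c(1, 0.5, 0)), 2)
  expect_error(overall_loss(-1, 0, 0, t = 1), "nonnegative")
  expect_error(overall_loss(1, 0, 0, t = -1), "step")
})
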