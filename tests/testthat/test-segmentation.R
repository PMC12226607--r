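# Segmentation contract: class weights, weighted CE, model forward, head
# expansion, confidence prediction, Dice.

make_ai <- function(class_id, mask, H = 4, W = 4) {
  annotated_image(array(0, c(H, W, 3)), class_id, mask)
}

test_that("class_frequency_weights follows inverse frequency", {
  reg <- class_registry(list(1:2))
  m1 <- matrix(0, 4, 4); m1[1:2, 1:4] <- 1       # 8 px class 1, 8 px bg
  m2 <- matrix(0, 4, 4); m2[1:2, 1:4] <- 1       # 8 px class 2, 8 px bg
  w <- class_frequency_weights(list(make_ai(1, m1), make_ai(2, m2)), reg)
  # bg has 16 px, classes 8 px each: equal class weights
  expect_equal(w[2], w[3])
  # class with 9x the pixels gets ~1/9 the weight (up to smoothing)
  m3 <- matrix(0, 4, 4); m3[1:3, 1:3] <- 1       # 9 px class 1
  m4 <- matrix(0, 4, 4); m4[1, 1] <- 1           # 1 px class 2
  w2 <- class_frequency_weights(list(make_ai(1, m3), make_ai(2, m4)), reg,
                                eps_f = 0)
  expect_equal(w2[3] / w2[2], 9)
  # absent class gets the maximum computed weight
  w3 <- suppressMessages(
    class_frequency_weights(list(make_ai(1, m3)), reg))
  expect_equal(w3[3], max(w3[1:2]))
  expect_error(class_frequency_weights(list(), reg), "empty")
})

test_that("weights normalize to mean 1 over present classes", {
  reg <- class_registry(list(1:3))
  set.seed(8)
  ds <- lapply(1:6, function(i) {
    m <- matrix(rbinom(16, 1, 0.3), 4, 4)
    if (sum(m) == 0) m[1, 1] <- 1
    make_ai(((i - 1) %% 3) + 1, m)
  })
  w <- class_frequency_weights(ds, reg)   # all classes present
  expect_equal(mean(w), 1)
  expect_true(all(w > 0))
  # single-class degenerate case: that class and background share all pixels
  m_all <- matrix(1, 4, 4)
  w1 <- suppressMessages(class_frequency_weights(list(make_ai(1, m_all)),
                                                 class_registry(list(1))))
  expect_equal(w1[2], 1)  # only class 1 present: normalized weight 1
})

test_that("weighted_cross_entropy closed forms and ignore handling", {
  # uniform logits over 2 channels -> ln 2
  logits <- array(0, c(2, 2, 2))
  labels <- matrix(c(0L, 1L, 0L, 1L), 2)
  expect_equal(weighted_cross_entropy(logits, labels, c(1, 1)), log(2))
  # near-perfect prediction -> ~0
  hot <- array(0, c(2, 2, 2)); hot[, , 2] <- 50
  ones <- matrix(1L, 2, 2)
  expect_lt(weighted_cross_entropy(hot, ones, c(1, 1)), 1e-10)
  # all ignored -> 0 with warning
  ig <- matrix(255L, 2, 2)
  expect_warning(v <- weighted_cross_entropy(logits, ig, c(1, 1)), "ignored")
  expect_equal(v, 0)
  # out-of-range label
  expect_error(weighted_cross_entropy(logits, matrix(3L, 2, 2), c(1, 1)),
               "label")
})

test_that("uniform-weight CE equals the unweighted mean cross-entropy", {
  set.seed(5)
  for (rep in 1:5) {
    K1 <- sample(2:5, 1)
    logits <- array(rnorm(6 * 6 * K1), c(6, 6, K1))
    labels <- matrix(sample(c(0:(K1 - 1), 255L), 36, replace = TRUE), 6)
    if (all(labels == 255)) labels[1, 1] <- 0L
    w <- weighted_cross_entropy(logits, labels, rep(1, K1))
    # independent oracle: plain softmax CE averaged over non-ignored pixels
    L <- matrix(logits, 36, K1)
    y <- as.vector(labels)
    keep <- y != 255
    p <- exp(L) / rowSums(exp(L))
    oracle <- mean(-log(p[cbind(which(keep), y[keep] + 1)]))
    expect_equal(w, oracle, tolerance = 1e-9)
  }
})

test_that("seg_forward honors the outputs contract deterministically", {
  net <- new_seg_net(3, n_classes = 4, width = 8, seed = 3)
  img <- array(runif(16 * 16 * 3, -1, 1), c(16, 16, 3))
  o1 <- seg_forward(net, img)
  o2 <- seg_forward(net, img)
  expect_identical(o1$logits, o2$logits)
  expect_identical(dim(o1$logits), c(16L, 16L, 5L))
  expect_length(o1$embeddings, 3)          # the declared distillation set L
  expect_named(o1$embeddings, c("encoder", "context", "logits"))
  expect_length(o1$encoder_feature, 8)
  expect_error(seg_forward(net, array(0, c(16, 16, 1))), "channels")
})

test_that("head expansion preserves old-class logits bit-for-bit", {
  net <- new_seg_net(3, n_classes = 3, width = 8, seed = 10)
  img <- array(runif(16 * 16 * 3, -1, 1), c(16, 16, 3))
  before <- seg_forward(net, img)$logits
  net2 <- expand_head(net, 2, seed = 77)
  expect_equal(net2$n_classes, 5)
  after <- seg_forward(net2, img)$logits
  expect_identical(dim(after)[3], 6L)
  expect_identical(after[, , 1:4], before)
  # old parameters themselves are unchanged
  expect_identical(net2$par$head.W[, , , 1:4, drop = FALSE], net$par$head.W)
  expect_identical(net2$par$head.b[1:4], net$par$head.b)
})

test_that("predict_with_confidence: softmax values and tie rule", {
  logits <- array(0, c(1, 2, 2))
  logits[1, 1, ] <- c(10, 0)
  # pixel 2 stays tied at (0, 0): lowest channel index wins
  pred <- predict_with_confidence(list(logits = logits))
  expect_equal(pred$labels[1, 1], 0L)
  expect_equal(pred$confidence[1, 1], 1 / (1 + exp(-10)), tolerance = 1e-9)
  expect_equal(pred$labels[1, 2], 0L)
  expect_equal(pred$confidence[1, 2], 0.5)
  # uniform logits over K+1 channels -> confidence 1/(K+1)
  u <- array(0, c(2, 2, 5))
  pu <- predict_with_confidence(list(logits = u))
  expect_true(all(pu$confidence == 0.2))
})

test_that("dice_score: closed forms, symmetry, permutation invariance", {
  a <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(dice_score(a, a), 1.0)
  b <- matrix(c(0, 0, 1, 1), 2)
  expect_equal(dice_score(a, b), 0.0)
  p <- matrix(0, 2, 4); p[1, ] <- 1              # |P| = 4
  g <- matrix(0, 2, 4); g[, 1:2] <- 1            # |G| = 4, overlap 2
  expect_equal(dice_score(p, g), 0.5)
  # empty-mask conventions
  z <- matrix(0, 2, 2)
  expect_equal(dice_score(z, z), 1.0)
  expect_equal(dice_score(a, matrix(0, 2, 2)), 0.0)
  expect_error(dice_score(a, matrix(0, 3, 3)), "differ")
  set.seed(2)
  for (i in 1:5) {
    x <- matrix(rbinom(24, 1, 0.4), 4)
    y <- matrix(rbinom(24, 1, 0.4), 4)
    expect_equal(dice_score(x, y), dice_score(y, x))
    perm <- sample(24)
    expect_equal(dice_score(matrix(x[perm], 4), matrix(y[perm], 4)),
                 dice_score(x, y))
  }
})

test_that("class_registry validates disjointness and reserved ids", {
  expect_error(class_registry(list(1:3, 3:4)), "disjoint")
  expect_error(class_registry(list(c(0, 1))), "ids")
  expect_error(class_registry(list(c(1, 255))), "ids")
  reg <- class_registry(list(1:3, 4:5))
  expect_equal(known_classes(reg, 0), 1:3)
  expect_equal(known_classes(reg, 1), 1:5)
})
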