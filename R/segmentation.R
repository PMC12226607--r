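# Segmentation-model contract for the binary-annotation regime: a compact
# fully-convolutional backbone exposing logits, the intermediate embeddings
# used for distillation, and a pooled encoder feature for contrastive
# learning; plus class-frequency-weighted cross-entropy and Dice scoring.

BACKGROUND_ID <- 0L
IGNORE_ID <- 255L

#' Class registry: the ordered incremental class groups
#'
#' @param steps list of integer vectors, one per training step, pairwise
#'   disjoint; e.g. `list(1:3, 4:5)` for a 3-2 split. Ids 0 (background) and
#'   255 (ignore) are reserved.
#' @return a `class_registry` object.
#' @export
#' @examples
#' reg <- class_registry(list(1:3, 4:5))
#' known_classes(reg, 0)
class_registry <- function(steps) {
  steps <- lapply(steps, function(s) sort(as.integer(s)))
  all_ids <- unlist(steps)
  if (anyDuplicated(all_ids)) {
    stop_validation("class sets across steps must be pairwise disjoint")
  }
  if (any(all_ids %in% c(BACKGROUND_ID, IGNORE_ID)) || any(all_ids < 1)) {
    stop_validation("class ids must be >= 1 and exclude the ignore id 255")
  }
  structure(list(steps = steps, background = BACKGROUND_ID, ignore = IGNORE_ID),
            class = "class_registry")
}

#' Classes known after training step t (0-based)
#' @param registry a [class_registry()].
#' @param t step index, `0 .. length(steps) - 1`.
#' @return sorted integer vector of class ids (background excluded).
#' @export
known_classes <- function(registry, t) {
  stopifnot(inherits(registry, "class_registry"),
            t >= 0, t < length(registry$steps))
  sort(unlist(registry$steps[seq_len(t + 1)]))
}

#' @export
print.class_registry <- function(x, ...) {
  cat("<class_registry>",
      paste(vapply(x$steps, function(s) paste0("{", paste(s, collapse = ","), "}"),
                   character(1)), collapse = " -> "), "\n")
  invisible(x)
}

#' One image with its single-class binary annotation
#'
#' The binary-annotation regime: each image carries a pixel mask for exactly
#' one designated class; any other visible structures are unlabeled.
#'
#' @param image `[H, W, C]` grid in `[-1, 1]`.
#' @param class_id the annotated class (integer >= 1).
#' @param mask `H x W` 0/1 matrix.
#' @return an `annotated_image` object.
#' @export
annotated_image <- function(image, class_id, mask) {
  check_grid(image, 3, "image")
  if (!is.matrix(mask) || !identical(dim(mask), dim(image)[1:2])) {
    stop_validation("mask shape must match image H x W")
  }
  if (!all(mask %in% c(0, 1))) stop_validation("mask must be binary 0/1")
  if (class_id < 1 || class_id != floor(class_id)) {
    stop_validation("class_id must be an integer >= 1")
  }
  structure(list(image = image, class_id = as.integer(class_id),
                 mask = matrix(as.integer(mask), nrow(mask))),
            class = "annotated_image")
}

# ---- backbone ---------------------------------------------------------------

#' Create an untrained segmentation network
#'
#' A compact fully-convolutional encoder-decoder: a 3x3 encoder convolution, a
#' dilated 3x3 context convolution (standing in for atrous spatial pyramid
#' pooling at desk scale), and a 1x1 classification head. The model exposes
#' the embeddings used for dense distillation -- encoder feature map, context
#' output, and logits -- plus a globally pooled encoder feature `z` for
#' contrastive learning. The `seg_outputs` contract is backbone-agnostic, so
#' larger backbones can be slotted in behind the same interface.
#'
#' @param in_channels image channels.
#' @param n_classes number of foreground classes currently known (logits get
#'   `n_classes + 1` channels, channel 1 = background).
#' @param width hidden feature channels.
#' @param dilation dilation of the context convolution.
#' @param seed RNG seed for weight init.
#' @return a `seg_net` object.
#' @export
new_seg_net <- function(in_channels = 3L, n_classes, width = 16L,
                        dilation = 2L, seed = 1L) {
  stopifnot(n_classes >= 1)
  par <- with_seed(seed, {
    enc <- init_conv(3, in_channels, width)
    ctx <- init_conv(3, width, width)
    head <- init_conv(1, width, n_classes + 1L)
    list(enc.W = enc$W, enc.b = enc$b, ctx.W = ctx$W, ctx.b = ctx$b,
         head.W = head$W, head.b = head$b)
  })
  structure(list(par = par, in_channels = as.integer(in_channels),
                 width = as.integer(width), dilation = as.integer(dilation),
                 n_classes = as.integer(n_classes)),
            class = "seg_net")
}

#' @export
print.seg_net <- function(x, ...) {
  cat(sprintf("<seg_net> %d-channel input, width %d, %d classes + background\n",
              x$in_channels, x$width, x$n_classes))
  invisible(x)
}

# Batched forward pass with caches for backprop. x: [H, W, C, B].
seg_net_fwd <- function(net, x) {
  p <- net$par
  f1 <- conv_fwd(p$enc.W, p$enc.b, x, 1L)
  r1 <- relu_fwd(f1$out)
  f2 <- conv_fwd(p$ctx.W, p$ctx.b, r1$out, net$dilation)
  r2 <- relu_fwd(f2$out)
  fh <- conv_fwd(p$head.W, p$head.b, r2$out, 1L)
  z <- apply(r2$out, c(3, 4), mean)              # width x B pooled feature
  list(logits = fh$out, e1 = r1$out, e2 = r2$out, z = z,
       f1 = f1, r1 = r1, f2 = f2, r2 = r2, fh = fh)
}

# Backward pass. Accepts gradients w.r.t. logits, the two embedding maps, and
# the pooled feature z (any may be NULL). Returns parameter grads.
seg_net_bwd <- function(net, cache, d_logits = NULL, d_e1 = NULL, d_e2 = NULL,
                        d_z = NULL) {
  p <- net$par
  dims <- dim(cache$e2)
  if (is.null(d_logits)) d_logits <- array(0, dim(cache$logits))
  gh <- conv_bwd(p$head.W, cache$fh, d_logits)
  dr2 <- gh$dx
  if (!is.null(d_e2)) dr2 <- dr2 + d_e2
  if (!is.null(d_z)) {
    # z is the spatial mean of e2: broadcast dz / (H*W) over pixels
    hw <- dims[1] * dims[2]
    for (bi in seq_len(dims[4])) {
      dr2[, , , bi] <- dr2[, , , bi] + rep(d_z[, bi] / hw, each = hw)
    }
  }
  d2 <- relu_bwd(cache$r2, dr2)
  g2 <- conv_bwd(p$ctx.W, cache$f2, d2)
  dr1 <- g2$dx
  if (!is.null(d_e1)) dr1 <- dr1 + d_e1
  d1 <- relu_bwd(cache$r1, dr1)
  g1 <- conv_bwd(p$enc.W, cache$f1, d1)
  list(enc.W = g1$dW, enc.b = g1$db, ctx.W = g2$dW, ctx.b = g2$db,
       head.W = gh$dW, head.b = gh$db)
}

#' Run the segmentation model on one image
#'
#' Generic over model representations: fitted `seg_net` objects and plain
#' functions `image -> seg_outputs` (useful for oracle stubs in evaluation
#' tests).
#'
#' @param model a `seg_net` or a function.
#' @param image `[H, W, C]` grid.
#' @return a `seg_outputs` object: `$logits` (`[H, W, K+1]`), `$embeddings`
#'   (ordered list `encoder`, `context`, `logits` -- the distillation layer
#'   set), `$encoder_feature` (pooled vector `z`).
#' @export
seg_forward <- function(model, image) UseMethod("seg_forward")

#' @export
seg_forward.function <- function(model, image) model(image)

#' @export
seg_forward.seg_net <- function(model, image) {
  check_grid(image, 3, "image")
  if (dim(image)[3] != model$in_channels) {
    stop_validation("image has %d channels, model expects %d",
                    dim(image)[3], model$in_channels)
  }
  fwd <- seg_net_fwd(model, array(image, c(dim(image), 1L)))
  logits <- drop_batch(fwd$logits)
  structure(list(logits = logits,
                 embeddings = list(encoder = drop_batch(fwd$e1),
                                   context = drop_batch(fwd$e2),
                                   logits = logits),
                 encoder_feature = fwd$z[, 1]),
            class = "seg_outputs")
}

#' Expand the classification head for newly arriving classes
#'
#' Appends `n_new` output channels initialized with small random weights; all
#' pre-existing channel parameters (including background) are bit-identical
#' afterwards, so old-class logits are unchanged on any input.
#'
#' @param model a `seg_net`.
#' @param n_new number of new classes (>= 1).
#' @param seed RNG seed for the new channels' init.
#' @return the expanded `seg_net`.
#' @export
expand_head <- function(model, n_new, seed = 1L) {
  stopifnot(n_new >= 1)
  old_W <- model$par$head.W                      # [1, 1, width, K_old + 1]
  k1 <- dim(old_W)[4]
  new_W <- array(0, c(1, 1, model$width, k1 + n_new))
  new_W[, , , seq_len(k1)] <- old_W
  new_W[, , , k1 + seq_len(n_new)] <-
    with_seed(seed, stats::rnorm(model$width * n_new, sd = 1e-3))
  model$par$head.W <- new_W
  model$par$head.b <- c(model$par$head.b, numeric(n_new))
  model$n_classes <- model$n_classes + as.integer(n_new)
  model
}

# ---- losses and scoring -----------------------------------------------------

#' Inverse-frequency class weights
#'
#' `weight_c` is proportional to `1 / (pixel count of c + eps_f)` with one
#' pixel of additive smoothing, normalized to mean 1 over the classes present
#' in the data. Background pixels (everything outside each image's mask) are
#' counted for the background class. A registry class absent from the dataset
#' receives the maximum computed weight (logged).
#'
#' @param dataset list of [annotated_image()] objects.
#' @param registry a [class_registry()]; weights cover background plus all
#'   registry classes.
#' @param eps_f additive smoothing, in pixels.
#' @return numeric vector of length `K + 1`; entry `c + 1` is the weight of
#'   class id `c` (entry 1 = background).
#' @export
class_frequency_weights <- function(dataset, registry, eps_f = 1) {
  if (length(dataset) == 0) stop_validation("empty dataset")
  ids <- sort(unlist(registry$steps))
  counts <- setNames(numeric(length(ids) + 1), c(0, ids))
  for (ai in dataset) {
    fg <- sum(ai$mask)
    counts[as.character(ai$class_id)] <-
      counts[as.character(ai$class_id)] + fg
    counts["0"] <- counts["0"] + length(ai$mask) - fg
  }
  weights_from_counts(counts, eps_f)
}

# Shared core: counts is a named vector over class ids (including "0").
weights_from_counts <- function(counts, eps_f = 1) {
  w <- 1 / (counts + eps_f)
  present <- counts > 0
  if (!any(present)) stop_validation("no labeled pixels in dataset")
  w <- w / mean(w[present])
  if (any(!present)) {
    w[!present] <- max(w[present])
    sr_log("warn", "classes absent from dataset get max weight:",
           paste(names(counts)[!present], collapse = ","))
  }
  unname(w)
}

# Internal batched weighted CE with gradient.
# logits: [H, W, K1, B]; labels: [H, W, B] integer (0..K1-1 or 255);
# weights: numeric(K1) indexed by class + 1.
wce_batch <- function(logits, labels, weights, want_grad = TRUE) {
  d <- dim(logits); K1 <- d[3]
  N <- d[1] * d[2] * d[4]
  L <- matrix(aperm(logits, c(1, 2, 4, 3)), N, K1)
  y <- as.vector(labels)
  bad <- y != IGNORE_ID & (y < 0 | y >= K1)
  if (any(bad)) {
    stop_validation("label value %d outside 0..%d", max(y[bad]), K1 - 1)
  }
  valid <- which(y != IGNORE_ID)
  if (length(valid) == 0) {
    warning("all pixels ignored; weighted cross-entropy is 0", call. = FALSE)
    return(list(loss = 0, grad = array(0, d)))
  }
  m <- L[, 1]
  for (k in seq_len(K1)[-1]) m <- pmax(m, L[, k])
  P <- exp(L - m)
  P <- P / rowSums(P)
  wy <- weights[y[valid] + 1]
  py <- P[cbind(valid, y[valid] + 1)]
  loss <- mean(wy * (-log(pmax(py, 1e-12))))
  if (!want_grad) return(list(loss = loss, grad = NULL))
  G <- matrix(0, N, K1)
  G[valid, ] <- P[valid, , drop = FALSE] * wy
  G[cbind(valid, y[valid] + 1)] <- G[cbind(valid, y[valid] + 1)] - wy
  G <- G / length(valid)
  grad <- aperm(array(G, c(d[1], d[2], d[4], K1)), c(1, 2, 4, 3))
  list(loss = loss, grad = grad)
}

#' Class-frequency-weighted cross-entropy
#'
#' Mean over non-ignored pixels of `weight[label] * (-log softmax(logits)[label])`.
#' Pixels labeled 255 are excluded; if every pixel is ignored the loss is 0
#' with a warning.
#'
#' @param logits `[H, W, K+1]` array.
#' @param labels `H x W` integer matrix with values in `0..K` or 255.
#' @param weights numeric vector of length `K + 1` (entry `c + 1` = class c).
#' @return nonnegative scalar.
#' @export
weighted_cross_entropy <- function(logits, labels, weights) {
  check_grid(logits, 3, "logits")
  if (!identical(dim(labels), dim(logits)[1:2])) {
    stop_validation("labels shape must match logits H x W")
  }
  if (length(weights) != dim(logits)[3]) {
    stop_validation("need one weight per logit channel")
  }
  wce_batch(array(logits, c(dim(logits), 1L)),
            array(labels, c(dim(labels), 1L)),
            weights, want_grad = FALSE)$loss
}

#' Per-pixel argmax label and softmax confidence
#'
#' Ties are broken toward the lowest channel index. Confidence is the softmax
#' probability of the selected channel.
#'
#' @param outputs a `seg_outputs` object (or any list with `$logits`).
#' @return list with `$labels` (`H x W` integer map, 0 = background) and
#'   `$confidence` (`H x W` values in `[0, 1]`).
#' @export
predict_with_confidence <- function(outputs) {
  logits <- outputs$logits
  check_grid(logits, 3, "logits")
  d <- dim(logits)
  L <- matrix(logits, d[1] * d[2], d[3])
  lab <- max.col(L, ties.method = "first")
  m <- L[cbind(seq_len(nrow(L)), lab)]
  conf <- 1 / rowSums(exp(L - m))
  list(labels = matrix(as.integer(lab - 1L), d[1], d[2]),
       confidence = matrix(conf, d[1], d[2]))
}

#' Dice overlap between two binary masks
#'
#' `2 |P & G| / (|P| + |G|)`; defined as 1 when both masks are empty and 0
#' when exactly one is empty.
#'
#' @param pred_mask,gt_mask 0/1 matrices of equal shape.
#' @return scalar in `[0, 1]`.
#' @export
#' @examples
#' dice_score(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))
dice_score <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask))) {
    stop_validation("mask shapes differ")
  }
  p <- sum(pred_mask != 0)
  g <- sum(gt_mask != 0)
  if (p + g == 0) return(1.0)
  2 * sum(pred_mask != 0 & gt_mask != 0) / (p + g)
}
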