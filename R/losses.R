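# The three-part incremental objective: dense feature distillation across the
# declared layer set, cross-model contrastive discrimination between real and
# generated images, pseudo-label merging, and the overall loss.

#' Dense feature-distillation loss
#'
#' Weighted sum over the distillation layer set of the Euclidean distance
#' between the frozen previous model's embedding and the current model's
#' embedding, each flattened: `sum_l omega_l * ||e_l_prev - e_l_curr||_2`.
#' A config switch substitutes the squared distance.
#'
#' @param prev_embeddings,curr_embeddings ordered lists of arrays with
#'   matching names and shapes (the layer set L).
#' @param omega named nonnegative layer weights covering exactly the layers of
#'   the embedding lists; an unnamed vector is matched positionally.
#' @param squared if TRUE use squared Euclidean distance.
#' @return nonnegative scalar.
#' @export
#' @examples
#' kd_loss(list(a = c(0, 0)), list(a = c(3, 4)), c(a = 1))  # 5
kd_loss <- function(prev_embeddings, curr_embeddings, omega, squared = FALSE) {
  if (length(prev_embeddings) != length(curr_embeddings)) {
    stop_validation("embedding lists have different lengths")
  }
  omega <- align_omega(omega, prev_embeddings)
  total <- 0
  for (l in seq_along(prev_embeddings)) {
    a <- prev_embeddings[[l]]; b <- curr_embeddings[[l]]
    if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
      stop_validation("embedding shapes differ at layer %d", l)
    }
    d2 <- sum((a - b)^2)
    total <- total + omega[l] * (if (squared) d2 else sqrt(d2))
  }
  total
}

align_omega <- function(omega, embeddings) {
  if (length(omega) != length(embeddings)) {
    stop_validation("omega must weight exactly the %d distillation layers",
                    length(embeddings))
  }
  if (any(omega < 0)) stop_validation("layer weights must be nonnegative")
  if (!is.null(names(omega)) && !is.null(names(embeddings))) {
    if (!setequal(names(omega), names(embeddings))) {
      stop_validation("omega names do not match the layer set")
    }
    omega <- omega[names(embeddings)]
  }
  as.numeric(omega)
}

# Gradient of kd_loss w.r.t. the current embeddings (list of arrays).
kd_grad <- function(prev_embeddings, curr_embeddings, omega, squared = FALSE) {
  omega <- align_omega(omega, prev_embeddings)
  grads <- vector("list", length(curr_embeddings))
  names(grads) <- names(curr_embeddings)
  for (l in seq_along(curr_embeddings)) {
    diff <- curr_embeddings[[l]] - prev_embeddings[[l]]
    if (squared) {
      grads[[l]] <- omega[l] * 2 * diff
    } else {
      nrm <- sqrt(sum(diff^2))
      grads[[l]] <- if (nrm < 1e-12) diff * 0 else omega[l] * diff / nrm
    }
  }
  grads
}

# ---- projection head --------------------------------------------------------

#' Create a projection head for contrastive learning
#'
#' Two affine layers with a ReLU between, followed by L2 normalization so that
#' projected dot products are cosines.
#'
#' @param in_dim input feature dimension (the pooled encoder feature `z`).
#' @param hidden_dim,out_dim layer sizes.
#' @param seed RNG seed for init.
#' @return a `projection_head` object.
#' @export
new_projection_head <- function(in_dim, hidden_dim = 64L, out_dim = 64L,
                                seed = 1L) {
  par <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(hidden_dim * in_dim, sd = sqrt(2 / in_dim)),
                hidden_dim, in_dim),
    b1 = numeric(hidden_dim),
    W2 = matrix(stats::rnorm(out_dim * hidden_dim, sd = sqrt(1 / hidden_dim)),
                out_dim, hidden_dim),
    b2 = numeric(out_dim)))
  structure(list(par = par, in_dim = as.integer(in_dim),
                 out_dim = as.integer(out_dim)),
            class = "projection_head")
}

#' Project a feature vector to the unit sphere
#'
#' @param head a [new_projection_head()].
#' @param z numeric feature vector of length `head$in_dim`.
#' @return unit-norm vector of length `head$out_dim`.
#' @export
project <- function(head, z) {
  project_fwd(head, z)$p
}

project_fwd <- function(head, z) {
  if (length(z) != head$in_dim) {
    stop_validation("feature has length %d, head expects %d",
                    length(z), head$in_dim)
  }
  p <- head$par
  h_pre <- drop(p$W1 %*% z) + p$b1
  h <- pmax(h_pre, 0)
  u <- drop(p$W2 %*% h) + p$b2
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) {
    # degenerate direction: fall back to the first basis vector
    pvec <- c(1, numeric(head$out_dim - 1))
  } else {
    pvec <- u / nu
  }
  list(p = pvec, u = u, nu = nu, h = h, h_pre = h_pre, z = z)
}

# Backprop dL/dp through normalization and the two affine layers.
# Returns head-parameter grads plus dz.
project_bwd <- function(head, cache, dp) {
  p <- head$par
  if (cache$nu < 1e-12) {
    zero <- lapply(p, function(x) x * 0)
    return(c(zero, list(dz = numeric(head$in_dim))))
  }
  du <- (dp - cache$p * sum(dp * cache$p)) / cache$nu
  dW2 <- du %o% cache$h
  db2 <- du
  dh <- drop(crossprod(p$W2, du))
  dh[cache$h_pre <= 0] <- 0
  dW1 <- dh %o% cache$z
  db1 <- dh
  dz <- drop(crossprod(p$W1, dh))
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, dz = dz)
}

#' Bundle the four encoder features entering one contrastive comparison
#'
#' @param z_t,z_tm1 features of one real image under the current and previous
#'   model.
#' @param zp_t,zp_tm1 features of one generated image under the two models.
#' @param tau temperature (> 0).
#' @return a `feature_bundle` object.
#' @export
feature_bundle <- function(z_t, z_tm1, zp_t, zp_tm1, tau = 0.1) {
  lens <- lengths(list(z_t, z_tm1, zp_t, zp_tm1))
  if (length(unique(lens)) != 1) {
    stop_validation("all four features must have the same dimension")
  }
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) {
    stop_validation("tau must be a positive scalar")
  }
  structure(list(z_t = z_t, z_tm1 = z_tm1, zp_t = zp_t, zp_tm1 = zp_tm1,
                 tau = tau),
            class = "feature_bundle")
}

#' Cross-model contrastive loss for one real/generated pairing
#'
#' InfoNCE with a single positive pair -- the real image's features under the
#' current and previous model -- and two negatives: the generated image's
#' features under either model. All four features pass through the projection
#' head (unit-normalized), and similarities are divided by the temperature:
#' `-log exp(s_pos) / (exp(s_pos) + exp(s_neg1) + exp(s_neg2))`.
#'
#' @param bundle a [feature_bundle()].
#' @param head a [new_projection_head()].
#' @return nonnegative scalar.
#' @export
contrastive_loss <- function(bundle, head) {
  contrastive_fwd(bundle, head)$loss
}

contrastive_fwd <- function(bundle, head) {
  ca <- project_fwd(head, bundle$z_t)
  cb <- project_fwd(head, bundle$z_tm1)
  cc_ <- project_fwd(head, bundle$zp_t)
  cd <- project_fwd(head, bundle$zp_tm1)
  sims <- c(sum(ca$p * cb$p), sum(ca$p * cc_$p), sum(ca$p * cd$p)) / bundle$tau
  m <- max(sims)
  lse <- m + log(sum(exp(sims - m)))
  list(loss = lse - sims[1], q = exp(sims - lse),
       ca = ca, cb = cb, cc = cc_, cd = cd)
}

# Loss + grads for training: head-parameter grads and gradients w.r.t. the
# current-model features z_t and zp_t (the frozen model's features receive no
# gradient, but the trainable head still does through all four projections).
contrastive_grad <- function(bundle, head) {
  fw <- contrastive_fwd(bundle, head)
  g <- (fw$q - c(1, 0, 0)) / bundle$tau     # dL / d sims
  a <- fw$ca$p; b <- fw$cb$p; cc_ <- fw$cc$p; d <- fw$cd$p
  dpa <- g[1] * b + g[2] * cc_ + g[3] * d
  dpb <- g[1] * a
  dpc <- g[2] * a
  dpd <- g[3] * a
  ga <- project_bwd(head, fw$ca, dpa)
  gb <- project_bwd(head, fw$cb, dpb)
  gc_ <- project_bwd(head, fw$cc, dpc)
  gd <- project_bwd(head, fw$cd, dpd)
  head_grads <- list(W1 = ga$W1 + gb$W1 + gc_$W1 + gd$W1,
                     b1 = ga$b1 + gb$b1 + gc_$b1 + gd$b1,
                     W2 = ga$W2 + gb$W2 + gc_$W2 + gd$W2,
                     b2 = ga$b2 + gb$b2 + gc_$b2 + gd$b2)
  list(loss = fw$loss, head = head_grads, d_z_t = ga$dz, d_zp_t = gc_$dz)
}

# ---- pseudo-labels and overall loss ----------------------------------------

#' Merge previous-model pseudo-labels with current ground truth
#'
#' Pixels inside the ground-truth mask always carry the annotated class.
#' Elsewhere the frozen previous model's argmax label is adopted wherever its
#' softmax confidence reaches `threshold` (background included); remaining
#' pixels get the ignore id 255 so uncertain regions never contribute to the
#' segmentation loss. For generated images (`gt = NULL`) the map is pure
#' thresholded pseudo-labels.
#'
#' @param prev_model_outputs `seg_outputs` of the frozen previous model.
#' @param gt an [annotated_image()] or NULL.
#' @param threshold confidence threshold in (0, 1).
#' @param registry a [class_registry()].
#' @return `H x W` integer label map.
#' @export
pseudo_label_merge <- function(prev_model_outputs, gt = NULL, threshold = 0.7,
                               registry) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop_validation("threshold must lie strictly in (0, 1)")
  }
  pred <- predict_with_confidence(prev_model_outputs)
  labels <- matrix(IGNORE_ID, nrow(pred$labels), ncol(pred$labels))
  keep <- pred$confidence >= threshold
  labels[keep] <- pred$labels[keep]
  if (!is.null(gt)) {
    if (!identical(dim(gt$mask), dim(labels))) {
      stop_validation("ground-truth mask shape mismatch")
    }
    labels[gt$mask == 1] <- gt$class_id
  }
  labels
}

#' Combine the three loss terms
#'
#' At the initial step (`t = 0`) only the segmentation term applies; at
#' incremental steps the three terms are summed (multipliers default to 1,
#' matching the unweighted formulation).
#'
#' @param seg_term,kd_term,cl_term nonnegative scalars.
#' @param t training step index (>= 0).
#' @param multipliers numeric length 3, applied to (seg, kd, cl) when `t > 0`.
#' @return nonnegative scalar.
#' @export
overall_loss <- function(seg_term, kd_term, cl_term, t,
                         multipliers = c(1, 1, 1)) {
  terms <- c(seg_term, kd_term, cl_term)
  if (any(!is.finite(terms)) || any(terms < 0)) {
    stop_validation("loss terms must be finite and nonnegative")
  }
  if (t < 0) stop_validation("step index must be >= 0")
  if (t == 0) return(seg_term)
  sum(multipliers * terms)
}
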