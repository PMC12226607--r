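# Orchestration of the T+1-step incremental protocol: step-0 training of the
# segmenter and the diffusion model, then per-step snapshotting/freezing of
# the previous model, head expansion, replay generation, pseudo-label
# merging, and joint optimization of the three-part objective.

#' @export
print.incremental_state <- function(x, ...) {
  cat(sprintf("<incremental_state> step %d, %d known classes, replay %s\n",
              x$t, length(known_classes(x$registry, x$t)),
              if (is.null(x$replay)) "none" else length(x$replay$images)))
  invisible(x)
}

check_step_classes <- function(dataset, expected, what) {
  got <- sort(unique(vapply(dataset, function(a) a$class_id, integer(1))))
  if (!all(got %in% expected)) {
    stop_validation("%s contains classes {%s} outside the step's set {%s}",
                    what, paste(setdiff(got, expected), collapse = ","),
                    paste(expected, collapse = ","))
  }
  invisible(got)
}

# Ground-truth-only label map: annotated class inside the mask, background
# elsewhere (the fine-tuning regime; no pseudo-labels).
gt_label_map <- function(ai) {
  lab <- matrix(BACKGROUND_ID, nrow(ai$mask), ncol(ai$mask))
  lab[ai$mask == 1] <- ai$class_id
  lab
}

# Inverse-frequency class weights from a list of label maps (ignore excluded).
weights_from_labels <- function(label_maps, n_channels) {
  counts <- numeric(n_channels)
  for (lab in label_maps) {
    tb <- tabulate(lab[lab != IGNORE_ID] + 1L, nbins = n_channels)
    counts <- counts + tb
  }
  names(counts) <- 0:(n_channels - 1)
  weights_from_counts(counts)
}

#' Run the initial training step
#'
#' Trains the step-0 segmentation model with class-frequency-weighted
#' cross-entropy only, and (unless disabled) the diffusion model on the same
#' images; the diffusion model is then frozen for all later steps.
#'
#' @param dataset_0 list of [annotated_image()] covering only step-0 classes.
#' @param registry a [class_registry()]; class ids must be contiguous `1..K`
#'   in step order so that logit channel `c + 1` serves class `c`.
#' @param config a [default_config()]-shaped list.
#' @return an `incremental_state` at `t = 0` (with `$prev_model = NULL`).
#' @export
run_initial_step <- function(dataset_0, registry, config = default_config()) {
  step0 <- registry$steps[[1]]
  if (!identical(step0, seq_along(step0))) {
    stop_validation("trainer requires contiguous class ids starting at 1")
  }
  if (length(dataset_0) == 0) stop_validation("empty step-0 dataset")
  check_step_classes(dataset_0, step0, "step-0 dataset")
  seed <- config$seed
  net <- new_seg_net(in_channels = config$image$C, n_classes = length(step0),
                     width = config$seg$width, dilation = config$seg$dilation,
                     seed = derive_seed(seed, "seg", "init", 0))
  labels <- lapply(dataset_0, gt_label_map)
  weights <- weights_from_labels(labels, length(step0) + 1L)
  trained <- train_seg_step(net, prev = NULL, head = NULL,
                            images = lapply(dataset_0, `[[`, "image"),
                            labels = labels,
                            replay_images = list(), replay_labels = list(),
                            weights = weights, t = 0L, config = config,
                            seed = derive_seed(seed, "seg", "train", 0))
  diff_net <- NULL
  sched <- build_linear_schedule(config$diffusion$S, config$diffusion$beta_start,
                                 config$diffusion$beta_end)
  if (isTRUE(config$diffusion$enabled)) {
    sr_log("info", "training diffusion model on step-0 images")
    diff_net <- fit_diffusion(lapply(dataset_0, `[[`, "image"), sched,
                              epochs = config$diffusion$epochs,
                              batch_size = config$diffusion$batch_size,
                              lr = config$diffusion$lr,
                              width = config$diffusion$width,
                              emb_dim = config$diffusion$emb_dim,
                              seed = derive_seed(seed, "diffusion"))
  }
  structure(list(t = 0L, prev_model = NULL, curr_model = trained$net,
                 registry = registry, diffusion = diff_net, sched = sched,
                 replay = NULL, head = NULL,
                 history = list(list(step = 0L, loss_trace = trained$trace)),
                 config = config),
            class = "incremental_state")
}

#' Run one incremental step
#'
#' Snapshots and freezes the previous model, expands the classification head
#' for the step's new classes, generates (or reuses) the diffusion replay
#' set, merges pseudo-labels with ground truth, and optimizes the overall
#' objective: weighted cross-entropy plus feature distillation plus the
#' cross-model contrastive term, as enabled by the config's method switches.
#'
#' @param state the `incremental_state` returned by the previous step.
#' @param dataset_t list of [annotated_image()] covering only step-t classes.
#' @param config optional config override (defaults to the state's).
#' @return the updated `incremental_state` at `t + 1`.
#' @export
run_incremental_step <- function(state, dataset_t, config = state$config) {
  t <- state$t + 1L
  if (t + 1L > length(state$registry$steps)) {
    stop_validation("registry defines no step %d", t)
  }
  new_cls <- state$registry$steps[[t + 1L]]
  known <- known_classes(state$registry, state$t)
  if (length(intersect(new_cls, known))) {
    stop_validation("step classes overlap previously known classes")
  }
  if (!identical(new_cls, max(known) + seq_along(new_cls))) {
    stop_validation("trainer requires step classes to continue the contiguous 1..K ids")
  }
  check_step_classes(dataset_t, new_cls, sprintf("step-%d dataset", t))
  seed <- config$seed
  ls <- config$losses

  prev <- state$curr_model                      # frozen snapshot of M^{t-1}
  curr <- expand_head(prev, length(new_cls),
                      seed = derive_seed(seed, "expand", t))
  n_ch <- curr$n_classes + 1L

  replay_images <- list()
  if (isTRUE(ls$use_replay)) {
    if (is.null(state$diffusion)) {
      stop_validation("replay requested but no diffusion model was trained")
    }
    if (is.null(state$replay) || isTRUE(config$diffusion$regenerate_per_step)) {
      sr_log("info", sprintf("generating replay set of %d images", config$replay$N))
      state$replay <- generate_replay_set(
        state$diffusion, state$sched, config$replay$N,
        c(config$image$H, config$image$W, config$image$C),
        derive_seed(seed, "replay-gen", t))
    }
    replay_images <- state$replay$images
  }

  # Labels: ground truth merged with thresholded previous-model pseudo-labels
  # for real images; pure pseudo-labels for generated images.
  labels <- lapply(dataset_t, function(ai) {
    if (isTRUE(ls$use_pseudo)) {
      pseudo_label_merge(seg_forward(prev, ai$image), gt = ai,
                         threshold = ls$threshold, registry = state$registry)
    } else {
      gt_label_map(ai)
    }
  })
  replay_labels <- lapply(replay_images, function(img) {
    pseudo_label_merge(seg_forward(prev, img), gt = NULL,
                       threshold = ls$threshold, registry = state$registry)
  })
  weights <- weights_from_labels(c(labels, replay_labels), n_ch)

  head <- state$head
  if (isTRUE(ls$use_cl) && is.null(head)) {
    head <- new_projection_head(curr$width, config$head$hidden,
                                config$head$out,
                                seed = derive_seed(seed, "projhead"))
  }

  trained <- train_seg_step(curr, prev = prev, head = head,
                            images = lapply(dataset_t, `[[`, "image"),
                            labels = labels,
                            replay_images = replay_images,
                            replay_labels = replay_labels,
                            weights = weights, t = t, config = config,
                            seed = derive_seed(seed, "seg", "train", t))

  state$prev_model <- prev
  state$curr_model <- trained$net
  state$head <- trained$head
  state$t <- t
  state$config <- config
  state$history <- c(state$history,
                     list(list(step = t, loss_trace = trained$trace)))
  state
}

#' Deterministic batch composition mixing real and replay images
#'
#' Each epoch visits every real image exactly once (shuffled), chunked so
#' that each batch carries `batch_size - ceiling(ratio * batch_size)` real
#' images plus `ceiling(ratio * batch_size)` replay images sampled uniformly
#' with replacement (0 when the replay set is empty or `ratio = 0`).
#'
#' @param n_real number of real images (>= 1).
#' @param n_replay size of the replay pool (0 disables replay slots).
#' @param batch_size total batch size (>= 2).
#' @param ratio replay fraction in `[0, 1)`.
#' @param rng_seed seed controlling shuffle and replay draws.
#' @return list of batches, each `list(real = indices, replay = indices)`.
#' @export
mix_batches <- function(n_real, n_replay, batch_size, ratio, rng_seed) {
  if (n_real < 1) stop_validation("empty real set")
  if (batch_size < 2) stop_validation("batch_size must be >= 2")
  if (ratio < 0 || ratio >= 1) stop_validation("ratio must lie in [0, 1)")
  n_rep_batch <- if (n_replay > 0) ceiling(ratio * batch_size) else 0L
  n_real_batch <- batch_size - n_rep_batch
  with_seed(rng_seed, {
    ord <- sample.int(n_real)
    starts <- seq(1, n_real, by = n_real_batch)
    lapply(starts, function(st) {
      real <- ord[st:min(st + n_real_batch - 1, n_real)]
      replay <- if (n_rep_batch > 0) {
        sample.int(n_replay, n_rep_batch, replace = TRUE)
      } else integer(0)
      list(real = real, replay = replay)
    })
  })
}

# Core optimization loop shared by the initial and incremental steps.
# images/labels: the step's real data; replay_images/replay_labels: generated
# data with pseudo-labels (may be empty). Returns the trained net, the
# (possibly updated) projection head, and the per-epoch mean overall loss.
train_seg_step <- function(net, prev, head, images, labels, replay_images,
                           replay_labels, weights, t, config, seed) {
  cs <- config$seg
  ls <- config$losses
  use_kd <- t > 0 && isTRUE(ls$use_kd) && !is.null(prev)
  use_cl <- t > 0 && isTRUE(ls$use_cl) && !is.null(head) &&
    length(replay_images) > 0
  n_prev_ch <- if (!is.null(prev)) prev$n_classes + 1L else 0L
  mult <- ls$multipliers
  state_opt <- opt_sgd_init(net$par)
  head_opt <- if (use_cl) opt_sgd_init(head$par) else NULL
  trace <- numeric(cs$epochs)
  for (ep in seq_len(cs$epochs)) {
    ep_seed <- derive_seed(seed, "epoch", ep)
    batches <- mix_batches(length(images), length(replay_images),
                           cs$batch_size,
                           if (length(replay_images)) config$replay$ratio else 0,
                           ep_seed)
    ep_loss <- numeric(0)
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      xs <- c(images[b$real], replay_images[b$replay])
      ys <- c(labels[b$real], replay_labels[b$replay])
      n_real_b <- length(b$real)
      B <- length(xs)
      x4 <- stack_grids(xs)
      lab3 <- array(unlist(ys), c(dim(xs[[1]])[1:2], B))
      fwd <- seg_net_fwd(net, x4)
      ce <- wce_batch(fwd$logits, lab3, weights)
      d_logits <- ce$grad
      d_e1 <- NULL; d_e2 <- NULL; d_z <- NULL
      kd_val <- 0; cl_val <- 0
      head_grads <- NULL
      if (use_kd || use_cl) pfwd <- seg_net_fwd(prev, x4)
      if (use_kd) {
        # Scale-matched layer weights: each layer's Euclidean distance is
        # normalized by sqrt(#elements) (an RMS distance), so the configured
        # omega are scale-free multipliers comparable to the mean-reduced
        # cross-entropy term regardless of layer size.
        omega_eff <- align_omega(ls$omega, list(encoder = 1, context = 1,
                                                logits = 1)) /
          sqrt(c(prod(dim(fwd$e1)[1:3]), prod(dim(fwd$e2)[1:3]),
                 prod(dim(fwd$logits)[1:2]) * n_prev_ch))
        names(omega_eff) <- c("encoder", "context", "logits")
        d_e1 <- array(0, dim(fwd$e1)); d_e2 <- array(0, dim(fwd$e2))
        for (ii in seq_len(B)) {
          pe <- list(encoder = pfwd$e1[, , , ii],
                     context = pfwd$e2[, , , ii],
                     logits = pfwd$logits[, , , ii])
          cekd <- list(encoder = fwd$e1[, , , ii],
                       context = fwd$e2[, , , ii],
                       logits = fwd$logits[, , seq_len(n_prev_ch), ii])
          kd_val <- kd_val + kd_loss(pe, cekd, omega_eff, ls$kd_squared)
          gk <- kd_grad(pe, cekd, omega_eff, ls$kd_squared)
          sc <- mult[["kd"]] / B
          d_e1[, , , ii] <- d_e1[, , , ii] + sc * gk$encoder
          d_e2[, , , ii] <- d_e2[, , , ii] + sc * gk$context
          d_logits[, , seq_len(n_prev_ch), ii] <-
            d_logits[, , seq_len(n_prev_ch), ii] + sc * gk$logits
        }
        kd_val <- kd_val / B
      }
      if (use_cl && length(b$replay) > 0 && n_real_b > 0) {
        d_z <- matrix(0, net$width, B)
        partners <- with_seed(derive_seed(ep_seed, "clpair", bi),
                              sample.int(length(b$replay), n_real_b,
                                         replace = TRUE))
        for (ri in seq_len(n_real_b)) {
          pj <- n_real_b + partners[ri]
          bundle <- feature_bundle(z_t = fwd$z[, ri], z_tm1 = pfwd$z[, ri],
                                   zp_t = fwd$z[, pj], zp_tm1 = pfwd$z[, pj],
                                   tau = ls$tau)
          gcl <- contrastive_grad(bundle, head)
          cl_val <- cl_val + gcl$loss
          sc <- mult[["cl"]] / n_real_b
          d_z[, ri] <- d_z[, ri] + sc * gcl$d_z_t
          d_z[, pj] <- d_z[, pj] + sc * gcl$d_zp_t
          head_grads <- acc_grads(head_grads,
                                  lapply(gcl$head, function(g) g * sc))
        }
        cl_val <- cl_val / n_real_b
      }
      # CE gradient carries the seg multiplier; KD/CL grads were scaled above
      if (t > 0 && mult[["seg"]] != 1) {
        d_logits <- d_logits + (mult[["seg"]] - 1) * ce$grad
      }
      grads <- seg_net_bwd(net, fwd, d_logits = d_logits, d_e1 = d_e1,
                           d_e2 = d_e2, d_z = d_z)
      upd <- opt_sgd_step(net$par, grads, state_opt, lr = cs$lr,
                          momentum = cs$momentum)
      net$par <- upd$par
      state_opt <- upd$state
      if (!is.null(head_grads)) {
        hupd <- opt_sgd_step(head$par, head_grads, head_opt, lr = cs$lr,
                             momentum = cs$momentum)
        head$par <- hupd$par
        head_opt <- hupd$state
      }
      ep_loss <- c(ep_loss, overall_loss(ce$loss, kd_val, cl_val, t, mult))
    }
    trace[ep] <- mean(ep_loss)
    sr_log("info", sprintf("step %d epoch %d/%d loss %.4f", t, ep, cs$epochs,
                           trace[ep]))
  }
  list(net = net, head = head, trace = trace)
}
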