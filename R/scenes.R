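# Synthetic surgical-like scenes: textured background, colored organ-like
# blobs, one binary mask per image for its designated "most prominent" class,
# and class-incremental splits on disjoint images. This makes the whole
# framework exercisable end-to-end with no downloads, at desk scale.

#' Specification of a synthetic scene distribution
#'
#' Each class has a distinct base color and texture amplitude; scenes place
#' 1-2 blobs (randomized superellipses with smooth shading plus Gaussian
#' texture) of the designated class over a low-frequency noise background,
#' optionally with 0-2 unannotated distractor blobs of other classes --
#' mimicking datasets where only the most prominent structure is annotated
#' while co-visible structures stay unlabeled.
#'
#' @param K number of classes (>= 2, <= 8 with the built-in palette).
#' @param size `c(H, W)`, each >= 16.
#' @param images_per_class default images per class for [build_dataset()].
#' @param blob_count_range integer range of designated-class blobs per scene.
#' @param radius_range blob semi-axis range as a fraction of `min(H, W)`.
#' @param fg_bounds admissible mask foreground fraction `c(lo, hi)`.
#' @param distractors if TRUE (default) scenes may contain unannotated blobs
#'   of other classes.
#' @param texture_amp per-class Gaussian texture standard deviation (recycled
#'   to K).
#' @return a `scene_spec` object.
#' @export
scene_spec <- function(K = 5L, size = c(32L, 32L), images_per_class = 60L,
                       blob_count_range = c(1L, 2L),
                       radius_range = c(0.12, 0.3),
                       fg_bounds = c(0.02, 0.5),
                       distractors = TRUE,
                       texture_amp = 0.08) {
  if (K < 2) stop_validation("need K >= 2 classes")
  if (any(size < 16)) stop_validation("scene size must be >= 16")
  palette <- scene_palette(K)
  structure(list(K = as.integer(K), H = as.integer(size[1]),
                 W = as.integer(size[2]),
                 images_per_class = as.integer(images_per_class),
                 colors = palette,
                 texture_amp = rep_len(texture_amp, K),
                 blob_count_range = as.integer(blob_count_range),
                 radius_range = radius_range, fg_bounds = fg_bounds,
                 distractors = isTRUE(distractors)),
            class = "scene_spec")
}

# Well-separated base colors in [-1, 1] RGB space.
scene_palette <- function(K) {
  base <- rbind(c(0.75, -0.25, -0.35),   # reddish (organ)
                c(-0.2, 0.65, -0.3),     # green
                c(-0.3, -0.2, 0.8),      # blue
                c(0.7, 0.65, -0.4),      # yellow
                c(0.7, -0.4, 0.7),       # magenta
                c(-0.4, 0.7, 0.7),       # cyan
                c(0.85, 0.35, 0.1),      # orange
                c(0.1, 0.1, 0.1))        # pale gray
  if (K > nrow(base)) stop_validation("built-in palette supports K <= %d", nrow(base))
  base[seq_len(K), , drop = FALSE]
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> K = %d, %dx%d, %d images/class, distractors %s\n",
              x$K, x$H, x$W, x$images_per_class,
              if (x$distractors) "on" else "off"))
  invisible(x)
}

# Bilinear upsample of a coarse [h, w] matrix to [H, W].
upsample_bilinear <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  yi <- (seq_len(H) - 0.5) / H * (h - 1) + 1
  xi <- (seq_len(W) - 0.5) / W * (w - 1) + 1
  y0 <- pmin(floor(yi), h - 1); x0 <- pmin(floor(xi), w - 1)
  fy <- yi - y0; fx <- xi - x0
  a <- m[y0, x0, drop = FALSE]; b <- m[y0 + 1, x0, drop = FALSE]
  cc <- m[y0, x0 + 1, drop = FALSE]; d <- m[y0 + 1, x0 + 1, drop = FALSE]
  a * outer(1 - fy, 1 - fx) + b * outer(fy, 1 - fx) +
    cc * outer(1 - fy, fx) + d * outer(fy, fx)
}

# Membership matrix of a randomized superellipse blob.
blob_mask <- function(H, W, cx, cy, ax, ay, theta, n) {
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), times = W), H, W)
  dx <- xs - cx; dy <- ys - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / ax
  v <- (-dx * sin(theta) + dy * cos(theta)) / ay
  (abs(u)^n + abs(v)^n) <= 1
}

draw_blob <- function(spec) {
  s <- min(spec$H, spec$W)
  rr <- spec$radius_range
  ax <- stats::runif(1, rr[1], rr[2]) * s
  ay <- stats::runif(1, rr[1], rr[2]) * s
  list(cx = stats::runif(1, 0.2 * spec$W, 0.8 * spec$W),
       cy = stats::runif(1, 0.2 * spec$H, 0.8 * spec$H),
       ax = ax, ay = ay,
       theta = stats::runif(1, 0, pi),
       n = stats::runif(1, 1.5, 3))
}

# Paint a blob onto img (H, W, 3): base color shaded by a smooth gradient
# plus Gaussian texture noise.
paint_blob <- function(img, member, color, amp) {
  H <- dim(img)[1]; W <- dim(img)[2]
  gdir <- stats::runif(2, -1, 1)
  xs <- matrix(rep(seq_len(W), each = H), H, W) / W - 0.5
  ys <- matrix(rep(seq_len(H), times = W), H, W) / H - 0.5
  shade <- 1 + 0.25 * (gdir[1] * xs + gdir[2] * ys)
  idx <- which(member)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[idx] <- color[ch] * shade[idx] +
      stats::rnorm(length(idx), sd = amp)
    img[, , ch] <- plane
  }
  img
}

#' Sample one annotated scene
#'
#' The returned image contains at least one blob of `class_id` (covered
#' exactly by the binary mask) and, when the distractor policy is on, up to
#' two unannotated blobs of other classes. The designated-class foreground
#' fraction is kept within `spec$fg_bounds` by redrawing.
#'
#' @param spec a [scene_spec()].
#' @param class_id the designated class in `1..K`.
#' @param rng_seed integer seed; the same seed reproduces the scene exactly.
#' @return an [annotated_image()].
#' @export
sample_scene <- function(spec, class_id, rng_seed) {
  if (class_id < 1 || class_id > spec$K) {
    stop_validation("class_id %d out of range 1..%d", class_id, spec$K)
  }
  with_seed(rng_seed, {
    H <- spec$H; W <- spec$W
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      coarse <- matrix(stats::rnorm(16, mean = -0.55, sd = 0.15), 4, 4)
      img[, , ch] <- upsample_bilinear(coarse, H, W) +
        stats::rnorm(H * W, sd = 0.03)
    }
    if (spec$distractors) {
      n_dis <- sample(0:2, 1)
      others <- setdiff(seq_len(spec$K), class_id)
      for (i in seq_len(n_dis)) {
        dc <- if (length(others) == 1) others else sample(others, 1)
        b <- draw_blob(spec)
        member <- blob_mask(H, W, b$cx, b$cy, b$ax, b$ay, b$theta, b$n)
        img <- paint_blob(img, member, spec$colors[dc, ], spec$texture_amp[dc])
      }
    }
    mask <- matrix(FALSE, H, W)
    for (try in 1:25) {
      cand <- matrix(FALSE, H, W)
      n_blob <- sample(spec$blob_count_range[1]:spec$blob_count_range[2], 1)
      blobs <- replicate(n_blob, draw_blob(spec), simplify = FALSE)
      for (b in blobs) {
        cand <- cand | blob_mask(H, W, b$cx, b$cy, b$ax, b$ay, b$theta, b$n)
      }
      frac <- mean(cand)
      if (frac >= spec$fg_bounds[1] && frac <= spec$fg_bounds[2]) {
        mask <- cand
        for (b in blobs) {
          member <- blob_mask(H, W, b$cx, b$cy, b$ax, b$ay, b$theta, b$n)
          img <- paint_blob(img, member, spec$colors[class_id, ],
                            spec$texture_amp[class_id])
        }
        break
      }
      if (try == 25) stop("could not place a blob within foreground bounds")
    }
    img <- pmin(pmax(img, -1), 1)
    annotated_image(img, class_id, mask * 1L)
  })
}

#' Build a balanced synthetic dataset with a manifest
#'
#' Generates `K * images_per_class` scenes (balanced per class), assigns a
#' deterministic 70/10/20 train/val/test split per class, and returns the
#' images alongside a manifest data frame with columns `id`, `class_id`,
#' `split`, `image_path`, `mask_path` (paths filled by [write_dataset()]).
#'
#' @param spec a [scene_spec()].
#' @param images_per_class images per class (defaults to the spec's value).
#' @param rng_seed master seed; scene i of class c uses a derived sub-seed.
#' @return a `scene_dataset`: `$items` (list of [annotated_image()]),
#'   `$manifest` (data frame).
#' @export
build_dataset <- function(spec, images_per_class = spec$images_per_class,
                          rng_seed = 1L) {
  if (images_per_class < 1) stop_validation("images_per_class must be >= 1")
  items <- list()
  rows <- list()
  for (cls in seq_len(spec$K)) {
    split <- split_labels(images_per_class,
                          derive_seed(rng_seed, "split", cls))
    for (i in seq_len(images_per_class)) {
      id <- sprintf("c%02d_i%03d", cls, i)
      items[[id]] <- sample_scene(spec, cls, derive_seed(rng_seed, "scene", cls, i))
      rows[[id]] <- data.frame(id = id, class_id = cls, split = split[i],
                               image_path = NA_character_,
                               mask_path = NA_character_,
                               stringsAsFactors = FALSE)
    }
  }
  structure(list(items = items, manifest = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 spec = spec),
            class = "scene_dataset")
}

split_labels <- function(n, seed) {
  n_train <- round(0.7 * n)
  n_val <- round(0.1 * n)
  lab <- c(rep("train", n_train), rep("val", n_val),
           rep("test", n - n_train - n_val))
  with_seed(seed, sample(lab))
}

#' @export
print.scene_dataset <- function(x, ...) {
  cat(sprintf("<scene_dataset> %d images, %d classes, splits: %s\n",
              length(x$items), x$spec$K,
              paste(names(table(x$manifest$split)),
                    table(x$manifest$split), sep = "=", collapse = " ")))
  invisible(x)
}

#' Partition a dataset into class-incremental step datasets
#'
#' Step t receives exactly the images whose annotated class belongs to the
#' registry's step-t set; because classes arrive on disjoint images, no image
#' appears in two steps.
#'
#' @param dataset a [build_dataset()] result.
#' @param registry a [class_registry()]; its class union must be covered by
#'   the dataset.
#' @return list with one element per step, each holding `$train`, `$val`,
#'   `$test` lists of [annotated_image()] plus `$classes`.
#' @export
make_incremental_splits <- function(dataset, registry) {
  mf <- dataset$manifest
  reg_ids <- unlist(registry$steps)
  missing <- setdiff(reg_ids, unique(mf$class_id))
  if (length(missing)) {
    stop_validation("registry classes absent from manifest: %s",
                    paste(missing, collapse = ","))
  }
  lapply(seq_along(registry$steps), function(ti) {
    cls <- registry$steps[[ti]]
    pick <- function(sp) {
      ids <- mf$id[mf$class_id %in% cls & mf$split == sp]
      dataset$items[ids]
    }
    list(classes = cls, train = pick("train"), val = pick("val"),
         test = pick("test"))
  })
}
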