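# Disk formats: PNG images and 0/255 PNG masks with a CSV manifest,
# replay-set export with a JSON provenance sidecar, and self-describing
# checkpoints for models + schedules.

# [-1, 1] grid <-> [0, 1] PNG intensities.
grid_to_png <- function(x) pmin(pmax((x + 1) / 2, 0), 1)
png_to_grid <- function(x) {
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  if (dim(x)[3] == 4) x <- x[, , 1:3, drop = FALSE]  # drop alpha
  x * 2 - 1
}

#' Write a dataset to disk as PNGs plus a CSV manifest
#'
#' Images go to `dir/images/<id>.png`, masks (0/255) to `dir/masks/<id>.png`,
#' and the manifest (columns `id`, `class_id`, `split`, `image_path`,
#' `mask_path`) to `dir/manifest.csv`. Paths in the manifest are relative to
#' `dir`.
#'
#' @param dataset a [build_dataset()] result.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  mf <- dataset$manifest
  for (i in seq_len(nrow(mf))) {
    id <- mf$id[i]
    ai <- dataset$items[[id]]
    img_rel <- file.path("images", paste0(id, ".png"))
    msk_rel <- file.path("masks", paste0(id, ".png"))
    png::writePNG(grid_to_png(ai$image), file.path(dir, img_rel))
    png::writePNG(ai$mask * 1.0, file.path(dir, msk_rel))
    mf$image_path[i] <- img_rel
    mf$mask_path[i] <- msk_rel
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(mf, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset from a manifest file
#'
#' @param manifest_path path to a `manifest.csv` as written by
#'   [write_dataset()] (or hand-built with the same columns); image/mask
#'   paths are resolved relative to the manifest's directory.
#' @return a `scene_dataset`-shaped list with `$items` and `$manifest`.
#' @export
read_manifest_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop_validation("manifest not found: %s", manifest_path)
  }
  mf <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("id", "class_id", "split", "image_path", "mask_path")
  if (!all(need %in% names(mf))) {
    stop_validation("manifest must have columns %s", paste(need, collapse = ", "))
  }
  base <- dirname(manifest_path)
  items <- list()
  for (i in seq_len(nrow(mf))) {
    img <- png_to_grid(png::readPNG(file.path(base, mf$image_path[i])))
    msk_raw <- png::readPNG(file.path(base, mf$mask_path[i]))
    if (length(dim(msk_raw)) == 3) msk_raw <- msk_raw[, , 1]
    items[[mf$id[i]]] <- annotated_image(img, mf$class_id[i],
                                         (msk_raw > 0.5) * 1L)
  }
  structure(list(items = items, manifest = mf, spec = NULL),
            class = "scene_dataset")
}

#' Export a replay set as PNGs with a JSON provenance sidecar
#'
#' @param replay a [generate_replay_set()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_replay_set <- function(replay, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(replay$images)) {
    png::writePNG(grid_to_png(replay$images[[i]]),
                  file.path(dir, sprintf("replay_%04d.png", i)))
  }
  jsonlite::write_json(replay$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Save a model checkpoint
#'
#' The container is self-describing: it embeds the object (network parameters
#' and architecture fields) together with any schedule arrays, so a
#' checkpoint can be sampled from without the original config.
#'
#' @param object a `noise_net`, `seg_net` or `incremental_state`.
#' @param path output `.rds` path.
#' @param sched optional [build_linear_schedule()] to embed alongside a
#'   `noise_net`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path, sched = NULL) {
  saveRDS(list(format = "segreplay-checkpoint-v1",
               class = class(object)[1], object = object, sched = sched),
          path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint path.
#' @return list with `$object` and (possibly NULL) `$sched`.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "segreplay-checkpoint-v1")) {
    stop_validation("not a segreplay checkpoint: %s", path)
  }
  x
}
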