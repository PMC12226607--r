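# Top-level driver: run the full multi-step protocol on a dataset and
# evaluate after each step in the grouped table layout.

#' Class-range groups implied by a registry
#'
#' One group per step range plus the cumulative "all known" group, named by
#' their id ranges (e.g. `"1-3"`, `"4-5"`, `"1-5"`).
#'
#' @param registry a [class_registry()].
#' @return named list of class-id vectors.
#' @export
registry_groups <- function(registry) {
  rng_name <- function(ids) {
    if (length(ids) == 1) as.character(ids) else
      sprintf("%d-%d", min(ids), max(ids))
  }
  groups <- lapply(registry$steps, identity)
  names(groups) <- vapply(groups, rng_name, character(1))
  all_ids <- sort(unlist(registry$steps))
  groups[[rng_name(all_ids)]] <- all_ids
  groups
}

#' Run the full class-incremental protocol
#'
#' Executes the initial step and every incremental step defined by the
#' registry, evaluating the current model after each step on the test images
#' of all classes known so far.
#'
#' @param splits per-step datasets from [make_incremental_splits()].
#' @param registry a [class_registry()].
#' @param config a [default_config()]-shaped list (use [method_config()] to
#'   select an ablation arm).
#' @return list with `$state` (final `incremental_state`) and `$reports`
#'   (one [step_report()] per step).
#' @export
run_protocol <- function(splits, registry, config = default_config()) {
  method <- config$method %||% "kd+dg+cl"
  state <- run_initial_step(splits[[1]]$train, registry, config)
  reports <- list(evaluate_state(state, splits, method))
  for (t in seq_len(length(registry$steps) - 1)) {
    state <- run_incremental_step(state, splits[[t + 1]]$train, config)
    reports <- c(reports, list(evaluate_state(state, splits, method)))
  }
  list(state = state, reports = reports)
}

#' Scaled-down forgetting benchmark across ablation arms
#'
#' Builds a synthetic dataset, trains the initial-step models once per seed
#' (the initial step is method-independent: segmentation-only loss plus the
#' diffusion model), then runs the incremental step under each ablation arm
#' and scores old-class and new-class mean Dice on the held-out test images.
#' This mirrors the fine-tuning-collapse and component-ablation comparisons
#' of incremental-segmentation result tables at desk scale.
#'
#' @param master_seed integer; per-repeat seeds are derived from it.
#' @param n_seeds number of independent repeats (median-friendly odd count).
#' @param methods ablation arms (see [method_config()]).
#' @param spec a [scene_spec()]; defaults to the 5-class 32x32 benchmark spec.
#' @param registry the incremental split; defaults to 3-2.
#' @param config base configuration.
#' @return data frame with columns `seed`, `method`, `old_dice`, `new_dice`.
#' @export
forgetting_benchmark <- function(master_seed = 1,
                                 n_seeds = 3,
                                 methods = c("fine-tune", "kd", "kd+dg",
                                             "kd+dg+cl"),
                                 spec = scene_spec(),
                                 registry = class_registry(list(1:3, 4:5)),
                                 config = default_config()) {
  dataset <- build_dataset(spec, rng_seed = derive_seed(master_seed, "bench-data"))
  splits <- make_incremental_splits(dataset, registry)
  test_all <- do.call(c, lapply(splits, `[[`, "test"))
  old_cls <- as.character(registry$steps[[1]])
  new_cls <- as.character(registry$steps[[2]])
  rows <- list()
  for (k in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- derive_seed(master_seed, "bench-seed", k)
    # initial step shared across arms (diffusion on so replay arms can use it)
    st0 <- run_initial_step(splits[[1]]$train, registry,
                            method_config(cfg, "kd+dg+cl"))
    for (m in methods) {
      st1 <- run_incremental_step(st0, splits[[2]]$train, method_config(cfg, m))
      pc <- evaluate_split(st1$curr_model, test_all, registry)
      rows[[length(rows) + 1]] <-
        data.frame(seed = k, method = m,
                   old_dice = mean(pc[old_cls]),
                   new_dice = mean(pc[new_cls]))
      sr_log("info", sprintf("benchmark seed %d %s: old %.3f new %.3f",
                             k, m, mean(pc[old_cls]), mean(pc[new_cls])))
    }
  }
  do.call(rbind, rows)
}

# Evaluate the current model on test images of every class known at step t.
evaluate_state <- function(state, splits, method) {
  t <- state$t
  test_set <- do.call(c, lapply(seq_len(t + 1), function(i) splits[[i]]$test))
  known_reg <- class_registry(state$registry$steps[seq_len(t + 1)])
  per_class <- evaluate_split(state$curr_model, test_set, known_reg)
  step_report(per_class, registry_groups(known_reg), t = t, method = method)
}
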