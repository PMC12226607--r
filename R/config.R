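#' Default run configuration
#'
#' Every tunable of the framework in one nested list; [load_run_config()]
#' merges a YAML file over these defaults. Desk-scale values are sized so the
#' full multi-step protocol runs in minutes on one CPU.
#'
#' @return nested list of settings.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    image = list(H = 32L, W = 32L, C = 3L),
    seg = list(width = 16L, dilation = 2L, epochs = 10L, batch_size = 8L,
               lr = 1e-2, momentum = 0.9),
    diffusion = list(enabled = TRUE, S = 50L, beta_start = 1e-4,
                     beta_end = 0.02, width = 16L, emb_dim = 16L,
                     epochs = 20L, batch_size = 16L, lr = 1e-3,
                     regenerate_per_step = FALSE),
    replay = list(N = 60L, ratio = 0.5),
    losses = list(omega = c(encoder = 1, context = 1, logits = 1),
                  tau = 0.1, threshold = 0.7,
                  multipliers = c(seg = 1, kd = 1, cl = 1),
                  kd_squared = FALSE,
                  use_pseudo = TRUE, use_kd = TRUE, use_replay = TRUE,
                  use_cl = TRUE),
    head = list(hidden = 64L, out = 64L),
    cache_pseudo_labels = TRUE
  )
}

#' Configure one of the benchmark method arms
#'
#' Maps an ablation tag to the loss/replay switches: `fine-tune` trains on
#' new ground truth only; `kd` adds feature distillation against the frozen
#' previous model; `kd+dg` adds diffusion replay together with the
#' pseudo-label integration (applied to both generated and real images);
#' `kd+dg+cl` (the full method) adds the contrastive term.
#'
#' @param config a [default_config()]-shaped list.
#' @param method one of `"fine-tune"`, `"kd"`, `"kd+dg"`, `"kd+dg+cl"`.
#' @return the adjusted config, with `$method` set.
#' @export
method_config <- function(config, method = c("kd+dg+cl", "kd+dg", "kd",
                                             "fine-tune")) {
  method <- match.arg(method)
  # flags: use_pseudo, use_kd, use_replay, use_cl
  flags <- switch(method,
    "fine-tune" = c(FALSE, FALSE, FALSE, FALSE),
    "kd"        = c(FALSE, TRUE,  FALSE, FALSE),
    "kd+dg"     = c(TRUE,  TRUE,  TRUE,  FALSE),
    "kd+dg+cl"  = c(TRUE,  TRUE,  TRUE,  TRUE))
  config$losses$use_pseudo <- flags[1]
  config$losses$use_kd <- flags[2]
  config$losses$use_replay <- flags[3]
  config$losses$use_cl <- flags[4]
  config$diffusion$enabled <- flags[3]
  config$method <- method
  config
}

#' Load a YAML run configuration over the defaults
#'
#' @param path YAML file; keys mirror [default_config()]. Missing keys keep
#'   their defaults.
#' @return merged config list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: %s", path)
  merge_config(default_config(), yaml::read_yaml(path))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}
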