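# Shared fixtures, built in code. Expensive objects are memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# A tiny 3-class 16x16 scene spec for fast unit tests.
tiny_spec <- function() scene_spec(K = 3, size = c(16, 16), images_per_class = 6)

tiny_dataset <- function() {
  memo("tiny_dataset", function() build_dataset(tiny_spec(), rng_seed = 7))
}

# A fast trainer config for unit tests (not the benchmark conditions).
tiny_config <- function(seed = 1) {
  cfg <- default_config()
  cfg$seed <- seed
  cfg$image <- list(H = 16L, W = 16L, C = 3L)
  cfg$seg$width <- 8L
  cfg$seg$epochs <- 3L
  cfg$diffusion$S <- 10L
  cfg$diffusion$epochs <- 2L
  cfg$diffusion$width <- 8L
  cfg$replay$N <- 4L
  cfg
}

# The desk-scale forgetting benchmark (minutes of compute); memoized so the
# acceptance checks share one run.
get_benchmark <- function() {
  memo("benchmark", function() suppressMessages(forgetting_benchmark(1)))
}

# Oracle segmentation "model": predicts the ground truth of a fixed lookup of
# annotated images with high-margin logits.
oracle_seg_model <- function(lookup, n_classes) {
  function(image) {
    key <- paste(round(as.vector(image), 6), collapse = ",")
    ai <- lookup[[key]]
    logits <- array(0, c(dim(image)[1:2], n_classes + 1))
    logits[, , 1] <- 10 * (ai$mask == 0)
    logits[cbind(which(ai$mask == 1, arr.ind = TRUE), ai$class_id + 1)] <- 10
    structure(list(logits = logits,
                   embeddings = list(encoder = logits, context = logits,
                                     logits = logits),
                   encoder_feature = numeric(4)),
              class = "seg_outputs")
  }
}

lookup_key <- function(image) paste(round(as.vector(image), 6), collapse = ",")

# Random unit-ish feature vector.
rfeat <- function(n, seed) with_seed_test(seed, stats::rnorm(n))

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
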