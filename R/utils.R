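#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed. Sub-seeds for
#' independent random streams (weight init, batch shuffling, per-image
#' sampling noise, ...) are derived by hashing the master seed together with a
#' string tag, so that adding a new stream never perturbs existing ones.
#'
#' @param master integer master seed.
#' @param ... character tags (and/or integers) identifying the stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "diffusion", "init")
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(master) %% m
  for (tag in list(...)) {
    for (code in utf8ToInt(paste0(as.character(tag), "|"))) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library code never disturbs the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Structured log line: timestamp + fields, suppressed below the active level.
#' @noRd
sr_log <- function(level = "info", ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  active <- getOption("segreplay.log_level", "warn")
  if (levels[[level]] < levels[[active]]) return(invisible(NULL))
  msg <- paste(vapply(list(...), function(x) paste(format(x), collapse = " "),
                      character(1)), collapse = " ")
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), level, msg))
  invisible(NULL)
}

stop_validation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' Check that a value is a finite numeric array with given number of dims
#' @noRd
check_grid <- function(x, ndim, what = "grid") {
  if (!is.numeric(x)) stop_validation("%s must be numeric", what)
  d <- dim(x)
  if (is.null(d) || length(d) != ndim) {
    stop_validation("%s must be a %d-d array, got dims [%s]",
                    what, ndim, paste(d, collapse = ", "))
  }
  invisible(x)
}
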