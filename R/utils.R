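# Internal helpers: seeded reproducibility and logging.

#' Derive a child seed from a parent seed and a path of labels
#'
#' Every stochastic stage of the pipeline (fold shuffling, subset
#' partitioning, per-CNN weight initialisation, per-tree bootstrap) draws
#' from its own stream, seeded deterministically from the global seed and
#' the stage's coordinates.  The result is always in `[1, 2^31 - 2]` so it
#' is a valid argument to [set.seed()].
#'
#' @param seed integer parent seed.
#' @param ... integers or strings identifying the sub-stream
#'   (e.g. fold index, CNN index, `"forest"`).
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(paste(x, collapse = ""))) else as.numeric(x)
  }), use.names = FALSE))
  m <- 2147483647  # 2^31 - 1, keeps exact double arithmetic below 2^53
  h <- 0
  for (p in parts) h <- (h * 69069 + (abs(p) %% m) + 1) %% m
  as.integer(h %% (m - 1) + 1)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# info-level logging; silence with options(cnnforest.verbose = FALSE)
cf_log <- function(...) {
  if (isTRUE(getOption("cnnforest.verbose", TRUE))) {
    message("[cnnforest] ", sprintf(...))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
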