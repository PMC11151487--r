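#' @keywords internal
"_PACKAGE"

## Lightweight structured logging. Every module funnels notable events
## (degenerate cases, dropped genes, applied offsets) through ps_log() so a
## run leaves an auditable trace; tests can capture it with ps_log_collect().

.pathsig_env <- new.env(parent = emptyenv())
.pathsig_env$log <- character(0)
.pathsig_env$collect <- FALSE

ps_log <- function(..., stage = "pathsig") {
  msg <- sprintf("[%s] %s", stage, paste0(...))
  if (isTRUE(.pathsig_env$collect)) {
    .pathsig_env$log <- c(.pathsig_env$log, msg)
  }
  message(msg)
  invisible(msg)
}

#' Capture package log records emitted during an expression
#'
#' Used by tests and the pipeline manifest to inspect degenerate-case
#' handling (zero-variance genes, applied count offsets, dropped samples).
#'
#' @param expr expression to evaluate
#' @return list with elements `value` and `log` (character vector of records)
#' @export
ps_log_collect <- function(expr) {
  old_collect <- .pathsig_env$collect
  old_log <- .pathsig_env$log
  .pathsig_env$collect <- TRUE
  .pathsig_env$log <- character(0)
  on.exit({
    .pathsig_env$collect <- old_collect
    .pathsig_env$log <- old_log
  })
  value <- suppressMessages(force(expr))
  list(value = value, log = .pathsig_env$log)
}

## Geometric mean; values must be strictly positive (callers offset counts
## where zeros are legal and log the offset).
geomean <- function(x) {
  stopifnot(all(is.finite(x)), all(x > 0))
  exp(mean(log(x)))
}

## Deterministic seed scoping: run expr under a local RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(round(seed) %% .Machine$integer.max))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
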