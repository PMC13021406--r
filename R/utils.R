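#' @keywords internal
"_PACKAGE"

# Condition helpers: all user-facing failures are classed conditions so the
# CLI can map them to exit codes (input vs config vs internal).

abort_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("funduseval_input_error", "funduseval_error")))
}

abort_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("funduseval_config_error", "funduseval_error")))
}

abort_internal <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("funduseval_internal_error", "funduseval_error")))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= min
}
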