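# Classed error conditions so callers (and the CLI) can distinguish bad
# input, violated preconditions, bad parameters and numerical failures.

nemo_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "nemo_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_input <- function(msg) nemo_stop("nemo_input_error", msg)
stop_param <- function(msg) nemo_stop("nemo_parameter_error", msg)
stop_precondition <- function(msg) nemo_stop("nemo_precondition_error", msg)
stop_numerical <- function(msg) nemo_stop("nemo_numerical_error", msg)

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-stream seeds derived from one user seed; kept within
# 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[i]) * 7919 + 1) %% 2147483647
  }
  as.integer(s)
}
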