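# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.  All stochastic operations in the package route through this
# so that identical seeds give identical results regardless of what the
# session did before.
with_rng_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-task seed from a master seed and a task index, staying
# within 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + as.numeric(index)) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so the CLI can map error classes to exit codes.
nfp_error <- function(msg, class) {
  stop(structure(
    class = c(class, "nfp_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

format_error   <- function(msg) nfp_error(msg, "nfp_format_error")
data_error     <- function(msg) nfp_error(msg, "nfp_data_error")
parameter_error <- function(msg) nfp_error(msg, "nfp_parameter_error")
config_error   <- function(msg) nfp_error(msg, "nfp_config_error")
external_error <- function(msg) nfp_error(msg, "nfp_external_error")
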