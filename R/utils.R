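# internal helpers shared across modules

#' @importFrom rlang abort
NULL

stop_format <- function(msg, ...) {
  rlang::abort(msg, class = c("sersquant_format_error", "sersquant_error"), ...)
}

stop_key <- function(msg, ...) {
  rlang::abort(msg, class = c("sersquant_key_error", "sersquant_error"), ...)
}

stop_value <- function(msg, ...) {
  rlang::abort(msg, class = c("sersquant_value_error", "sersquant_error"), ...)
}

stop_config <- function(msg, ...) {
  rlang::abort(msg, class = c("sersquant_config_error", "sersquant_error"), ...)
}

stop_shape <- function(msg, ...) {
  rlang::abort(msg, class = c("sersquant_shape_error", "sersquant_error"), ...)
}

stop_metric <- function(msg, ...) {
  rlang::abort(msg, class = c("sersquant_metric_error", "sersquant_error"), ...)
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had_old) get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (had_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a stage seed from a root seed
#'
#' One root seed fans out deterministically to the pipeline stages
#' (simulation, splitting, genetic search, gradient training) so that a whole
#' run is reproducible from a single integer. The derived seed always fits in
#' a 32-bit signed integer.
#'
#' @param seed Root seed (integer).
#' @param stage Stage offset (small non-negative integer).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage = 0L) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_value("`seed` must be a single finite number")
  }
  as.integer((abs(as.double(seed)) %% 2097143) * 1009 + as.double(stage) %% 1009)
}
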