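`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named substream seed from a master seed
#'
#' A master seed plus a stream name deterministically yields an integer seed
#' below 2^31, so that adding a generator to the pipeline never perturbs the
#' random numbers consumed by another.
#'
#' @param master integer master seed.
#' @param name character stream name, e.g. "cohort", "metrics".
#' @return a single integer seed in [0, 2^31 - 1].
#' @export
substream_seed <- function(master, name) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(name))
  h <- 0
  for (cc in utf8ToInt(name)) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(as.numeric(master)) * 2654435761 + h * 40503 + 17) %% 2147483647)
}

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores .Random.seed so generators are pure functions of their
#' own (config, seed) and never disturb the caller's stream.
#'
#' @param seed integer seed for the local stream.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_config <- function(...) {
  stop(structure(class = c("mscognet_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("mscognet_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_convergence <- function(...) {
  stop(structure(class = c("mscognet_convergence_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_config(what, " must lie in [0, 1]")
  invisible(x)
}
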