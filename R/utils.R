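#' Run code under a fixed RNG seed without disturbing the global stream
#'
#' Evaluates `expr` with the Mersenne-Twister stream seeded at `seed`; the
#' caller's `.Random.seed` is restored afterwards. With `seed = NULL` the
#' expression runs on the ambient stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a top-level seed
#'
#' Every stochastic stage of a run is seeded from one top-level seed through
#' this derivation (seed mixed with a hash of the stage name), so stages are
#' independently reproducible. The result is always in `[1, 2^31 - 2]`.
#'
#' @param seed Top-level integer seed.
#' @param stage Character stage name, e.g. `"genome"`.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, "genome")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  out <- (abs(seed) %% 2147483647) * 48271 %% 2147483647
  out <- (out + h * 16807) %% 2147483647
  as.integer(out %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_foldback <- function(msg, class, ...) {
  stop(structure(class = c(class, "foldback_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}
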