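# Internal helpers: argument checking, seeding, small numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_arg("`%s` must be a single finite number", name)
  if (positive && x <= 0)
    stop_arg("`%s` must be positive", name)
  invisible(x)
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level != as.integer(level) || level < 0 || level > 4)
    stop_arg("`level` must be an integer fatigue level in 0..4")
  as.integer(level)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Derive a stage-specific seed from a global seed
#'
#' Every random operation in the pipeline draws from a seed derived
#' deterministically from the global seed and a stage name, so that stages
#' can be re-run in isolation and still reproduce bit-identically.
#'
#' @param global_seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(global_seed, stage) {
  check_scalar_num(global_seed, "global_seed")
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  s <- (abs(global_seed) * 48271 + h * 16807) %% 2147483646
  as.integer(s + 1)
}

# Evaluate expr with a local RNG state (restores the caller's state after).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
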