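#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the global RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so generators are pure functions of their
#' arguments and never perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a stream seed from a base seed and context tags
#'
#' Deterministically combines a base seed with small integers or strings
#' (year, month, stream name) into a 31-bit seed, so every synthetic field and
#' ensemble year has its own reproducible stream and adding years never
#' perturbs existing ones.
#'
#' @param seed base integer seed.
#' @param ... integers or strings identifying the stream.
#' @return an integer in [0, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) {
      p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    }
    # 31-bit multiplicative mix; doubles are exact below 2^53
    h <- (h * 48271 + as.double(p) %% 2147483647) %% 2147483647
  }
  as.integer(h)
}
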