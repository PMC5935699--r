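# Internal numeric helpers shared across modules.

#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Run `code` under a fixed RNG seed without touching the caller's RNG
# stream. All generators in the package route their randomness through
# this so that a seed fully determines the output.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

#' @keywords internal
#' @noRd
stop_arg <- function(name, msg) {
  stop(sprintf("invalid `%s`: %s", name, msg), call. = FALSE)
}

#' @keywords internal
#' @noRd
check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_arg(name, "must be a single finite number")
  }
  invisible(x)
}
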