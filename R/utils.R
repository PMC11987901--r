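#' Derive a stream of child seeds from one top-level seed
#'
#' Reproducibility helper: every random stage of the pipeline receives its
#' own seed derived deterministically from a single top-level seed by a
#' counter scheme, so stages stay independent and re-runnable in isolation.
#'
#' @param seed Integer top-level seed.
#' @param stage Character stage label (hashed into the stream).
#' @param index Integer counter within the stage.
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(42, "phantom", 1)
derive_seed <- function(seed, stage, index = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # simple LCG-style mix, kept inside 31 bits
  x <- (as.double(seed) * 2654435761 + h * 97 + index * 1000003) %% 2147483647
  as.integer(x)
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the
#' caller's `.Random.seed`, so surrounding random state is unaffected.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
#' @examples
#' with_seed(1, runif(2))
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
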