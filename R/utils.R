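# Named seed streams: every source of randomness (pattern draws, noise,
# threshold heterogeneity, run schedules) gets its own derived seed so one
# source can be varied while the others stay fixed. Derived seeds stay below
# 2^31 - 1.
.stream_codes <- c(patterns = 1L, noise = 2L, heterogeneity = 3L,
                   runs = 4L, cue = 5L, misc = 6L)

#' Derive a named sub-seed from a master seed
#'
#' @param seed master integer seed.
#' @param purpose one of `"patterns"`, `"noise"`, `"heterogeneity"`, `"runs"`,
#'   `"cue"`, `"misc"`.
#' @param index integer index within the stream (e.g. run or pattern number).
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
stream_seed <- function(seed, purpose = "misc", index = 0L) {
  code <- .stream_codes[[match.arg(purpose, names(.stream_codes))]]
  m <- 2147483647
  x <- (as.double(seed) %% m)
  # two rounds of a Lehmer-style mix keep distinct (seed, purpose, index)
  # triples well separated
  x <- (x * 48271 + code * 2654435) %% m
  x <- (x * 48271 + index * 97561) %% m
  as.integer(x)
}

with_stream <- function(seed, purpose, index, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, purpose, index))
  force(expr)
}

stopifnot_scalar_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (positive && x <= 0)) {
    abort(sprintf("`%s` must be a single finite %snumber", name,
                  if (positive) "positive " else ""))
  }
  invisible(x)
}
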