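#' Derive a reproducible substream seed
#'
#' Maps a master seed plus a sequence of string/integer labels to an integer
#' seed below 2^31, so that independent parts of a simulation (cohort
#' generation, year-1 event draws, post-year-1 survival, each PSA draw) use
#' named, non-overlapping random streams.
#'
#' @param seed master integer seed.
#' @param ... labels (strings or integers) naming the substream.
#' @return an integer seed in \[0, 2^31 - 2\].
#' @export
substream_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  s <- paste(c(format(as.integer(seed)), as.character(unlist(list(...)))),
             collapse = "/")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

#' Evaluate code under a given seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded sub-computations do not perturb each other.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' = %g outside [%g, %g]", name, x, lower, upper),
         call. = FALSE)
  invisible(x)
}
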