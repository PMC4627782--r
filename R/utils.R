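# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched.  `seed = NULL` evaluates as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# Pull the numeric values and week indices out of an outcome series or a
# plain numeric vector (weeks default to 0, 1, ...).
series_values <- function(x) {
  if (inherits(x, "outcome_series")) return(x$values)
  if (is.numeric(x)) return(as.numeric(x))
  stop("expected an 'outcome_series' or a numeric vector")
}

series_weeks <- function(x) {
  if (inherits(x, "outcome_series")) return(x$calendar$observed_weeks)
  seq_along(series_values(x)) - 1
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
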