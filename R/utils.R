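# internal helpers shared across modules

# Run `code` with the RNG seeded to `seed`, restoring (or removing) the
# caller's .Random.seed afterwards so generators never leak global state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_input("`%s` must be a single number", name)
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper)
    stop_input("`%s` = %g out of range", name, x)
  invisible(x)
}
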