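# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded library calls never disturb the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is mandatory for stochastic calls", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stream sub-seed, kept strictly below 2^31 - 1.
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(stream) * 10007
  as.integer(s %% 2147483629) + 1L
}

# floor((x - origin)/width) made safe against decimal representation error:
# quantities written with <= 9 decimals land in the bin their printed value
# implies, never one below because of a 1-ulp shortfall.
decimal_floor_index <- function(x, origin, width) {
  q <- (x - origin) / width
  as.integer(floor(round(q, 9)))
}

stop_naquant <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "naquant_error")))
}
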