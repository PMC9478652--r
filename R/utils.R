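# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so deterministic draws
#' inside the package never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
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

# Stable integer hash of a small tuple, for per-epoch seed derivation.
# Keeps results in [0, 2^31 - 2] so they are valid R seeds.
stable_seed <- function(master, ...) {
  parts <- c(as.numeric(master), as.numeric(c(...)))
  h <- 0
  m <- 2147483647  # 2^31 - 1, prime
  for (p in parts) {
    h <- (h * 1103515245 + (p %% m) * 12345 + 12345) %% m
  }
  as.integer(h)
}

# Periodic Hann taper of length n.
hann_window <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
}

# Reflect-pad a vector by `pad` samples on each side (no edge repetition,
# librosa-style "reflect" mode).
reflect_pad <- function(x, pad) {
  n <- length(x)
  if (pad == 0) return(x)
  stopifnot(pad < n)
  c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == round(x) && x >= 0

# round-half-up, used for the 80/20 split and ms-to-sample conversion
round_half_up <- function(x) floor(x + 0.5)
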