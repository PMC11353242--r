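#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# take explicit seeds and route through here; nothing touches global RNG
# state as a side effect.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index, staying inside
# 32-bit integer range. Used so that one user-facing seed can drive several
# independent internal streams deterministically.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 1103) %% 2147483562) + 1L
}

# round() in R rounds half to even; copy-number calls need half away from
# zero (x.5 -> x+1 for positive x).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stopifnot_scalar_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
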