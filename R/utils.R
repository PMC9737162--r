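# internal helpers shared across the package

deg2rad <- function(x) x * (pi / 180)
rad2deg <- function(x) x * (180 / pi)

# Normalize an undirected line angle (degrees) into [0, 180).
norm_angle180 <- function(theta) {
  out <- theta %% 180
  # guard against 180 - eps rounding back to 180 after %%
  out[out >= 180] <- 0
  out
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. seed = NULL uses the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # force RNG initialisation so there is a state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Draw `n` integer sub-seeds derived deterministically from `seed`,
# kept strictly below .Machine$integer.max.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
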