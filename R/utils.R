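# Internal helpers: deterministic seeding and small assertions.

#' @useDynLib spikechain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `expr` under a temporary R RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Spawn named component sub-seeds from one master seed. Every source of
# randomness in a protocol (pattern, schedule, noise, initial weights, tests)
# gets its own stream so components can be varied independently.
spawn_seeds <- function(seed, names) {
  stopifnot(length(seed) == 1, is.finite(seed))
  s <- with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, length(names)))
  stats::setNames(s, names)
}

stop_if_not_scalar_pos <- function(x, what, strict = TRUE) {
  if (length(x) != 1 || !is.finite(x) || (if (strict) x <= 0 else x < 0)) {
    stop(sprintf("`%s` must be a single %s number", what,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}
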