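# Internal helpers shared across modules.

# Evaluate `expr` without disturbing the caller's RNG stream.  The population
# optimizer relies on this so that objective callbacks which seed their own
# training runs (the detector and the capsule network do) cannot collapse the
# optimizer's random draws onto a single stream.
isolate_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  expr
}

# Derive a child seed from a base seed; kept well below .Machine$integer.max.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset) %% 1009L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_numeric_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}
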