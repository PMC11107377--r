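# Seed handling: every randomized operation takes an explicit integer seed and
# restores the caller's RNG state afterwards, so package calls never perturb a
# user's stream. Ensembles derive one child seed per run from the root seed,
# making runs reproducible independently of evaluation order.

with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic child seed for run k (1-based); stays inside 32-bit range
child_seed <- function(seed, k) {
  as.integer((as.double(seed) + 1000003 * as.double(k)) %% 2147483647)
}
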