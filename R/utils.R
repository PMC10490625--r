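# Internal helpers: seeded RNG scoping, stage-tagged logging, seed expansion.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores
# the caller's RNG state afterwards so library code never clobbers it.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# One global seed expands deterministically into per-stage seeds so each
# stage is independently reproducible. Offsets are fixed and documented here.
stage_seeds <- function(seed) {
  seed <- as.integer(seed) %% 1000000000L
  list(simulate = seed,
       ica      = (seed + 101L) %% .Machine$integer.max,
       split    = (seed + 202L) %% .Machine$integer.max,
       tune     = (seed + 303L) %% .Machine$integer.max,
       train    = (seed + 404L) %% .Machine$integer.max,
       explain  = (seed + 505L) %% .Machine$integer.max)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper)
    stop(sprintf("`%s` must be a finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}
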