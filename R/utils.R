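# Internal helpers shared across modules.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic package code funnels through
# this so that a (config, seed) pair is fully reproducible and library calls
# never disturb the user's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
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

# Half-open interval overlap: does [a0, a1) intersect [b0, b1)?
intervals_overlap <- function(a0, a1, b0, b1) {
  a0 < b1 & b0 < a1
}

# Largest-remainder apportionment of `total` items proportionally to
# `weights` (non-negative), capped elementwise at `cap`. Deterministic:
# remainder ties broken by position.
apportion <- function(total, weights, cap = rep(Inf, length(weights))) {
  stopifnot(total >= 0, all(weights >= 0))
  if (total == 0 || sum(weights) == 0) return(integer(length(weights)))
  quota <- total * weights / sum(weights)
  n <- pmin(floor(quota), cap)
  left <- total - sum(n)
  # distribute remainders, skipping capped cells
  frac <- quota - floor(quota)
  ord <- order(-frac, seq_along(frac))
  i <- 1L
  while (left > 0 && i <= 2L * length(ord)) {
    j <- ord[((i - 1L) %% length(ord)) + 1L]
    if (n[j] < cap[j]) {
      n[j] <- n[j] + 1L
      left <- left - 1L
    }
    i <- i + 1L
  }
  as.integer(n)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
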