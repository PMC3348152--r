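# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never disturbs user
# simulations.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-frame seed below 2^31, derived from a base seed, the
# frame time (hours, resolved to 0.01 h) and a channel tag.
frame_seed <- function(base, time, channel = "bright") {
  chan <- if (identical(channel, "fluor")) 7901L else 0L
  (abs(as.integer(base)) %% 1000003L) * 2011L +
    (as.integer(round(time * 100)) %% 100003L) * 17L + chan
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Pairwise Euclidean distances between rows of (x, y) matrices a and b.
cross_dist <- function(ax, ay, bx, by) {
  dx <- outer(ax, bx, "-")
  dy <- outer(ay, by, "-")
  sqrt(dx * dx + dy * dy)
}

# Nearest-neighbour distance within one point set (Inf for a single point).
nn_dist <- function(x, y) {
  n <- length(x)
  if (n < 2) return(rep(Inf, n))
  d <- cross_dist(x, y, x, y)
  diag(d) <- Inf
  apply(d, 1, min)
}
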