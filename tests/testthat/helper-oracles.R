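# Independent brute-force oracles used to cross-check the package's
# statistics, plus tiny fixture builders shared across test files.

# Exact two-sided rank-sum p by full enumeration of all C(m+n, m) group
# assignments of the pooled ranks.
enum_rank_sum_p <- function(x, y) {
  pool <- c(x, y)
  N <- length(pool)
  m <- length(x)
  rk <- rank(pool)
  obs <- sum(rk[seq_len(m)])
  Ws <- apply(utils::combn(N, m), 2, function(i) sum(rk[i]))
  min(1, 2 * min(mean(Ws <= obs), mean(Ws >= obs)))
}

# Exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration:
# sum of all table probabilities not exceeding the observed one.
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  kk <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(kk, m, n, k)
  sum(pr[pr <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Independent least-squares slope (closed form, no lm / cov reuse).
ols_slope <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

# A small field with well-separated colonies for unit tests.
toy_field <- function(mus = c(0.3, 0, 0.45), seed = 7, size = 300,
                      fluor = c(0.5, 0.2, 0.1), areas = c(100, 314, 80)) {
  centers <- list(c(80, 80), c(200, 90), c(140, 210))
  cols <- lapply(seq_along(mus), function(i)
    colony_spec(letters[i], centers[[i]], areas[i], mus[i],
                fluorescence_level = fluor[i]))
  field_spec(size, size, cols, seed = seed)
}

# Segment every frame of a timelapse (bright channel), attaching
# fluorescence when present.
segment_series <- function(sim, params = segmentation_params()) {
  lapply(seq_along(sim$frames), function(k) {
    o <- dual_threshold_segment(sim$frames[[k]], params)
    if (!is.null(sim$fluor_frames))
      o$table <- measure_objects(o, sim$fluor_frames[[k]])
    o
  })
}

# Hand-built mc_objects from centroid/area tables, for tracking tests that
# need exact control over object positions without rendering images.
fake_objects <- function(time, x, y, area, feret = sqrt(4 * area / pi),
                         touches_edge = FALSE, labels = NULL) {
  n <- length(x)
  structure(list(
    labels = labels %||% matrix(0L, 4, 4),
    table = data.frame(label = seq_len(n), area_px = area, x = x, y = y,
                       feret_px = rep_len(feret, n),
                       touches_edge = rep_len(touches_edge, n),
                       fluor_density = NA_real_),
    time = time, well = "A1", field = 1L,
    thresholds = c(high = 0.6, low = 0.4)),
    class = "mc_objects")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
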