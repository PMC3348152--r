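test_that("growth-rate fitting is exact on clean exponentials", {
  t <- 0:8
  tp <- data.frame(track_id = 1, time = t, area_px = 120 * exp(0.4 * t))
  fit <- fit_specific_growth_rate(tp)
  expect_equal(fit$mu, 0.4, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_true(fit$included)
  expect_true(fit$divided)

  # invariant to rescaling areas by any positive constant
  tp2 <- tp; tp2$area_px <- tp$area_px * 37.5
  expect_equal(fit_specific_growth_rate(tp2)$mu, fit$mu, tolerance = 1e-12)

  flat <- data.frame(track_id = 2, time = t, area_px = rep(200, 9))
  ffit <- fit_specific_growth_rate(flat)
  expect_equal(ffit$mu, 0)
  expect_equal(ffit$r, 0)
  expect_true(ffit$degenerate_fit)
  expect_false(ffit$divided)

  short <- data.frame(track_id = 3, time = 0:3, area_px = exp(0.3 * (0:3)))
  sfit <- fit_specific_growth_rate(short)
  expect_false(sfit$included)
  expect_equal(sfit$exclusion_reason, "too_few_timepoints")

  expect_error(fit_specific_growth_rate(
    data.frame(track_id = 4, time = 0:5, area_px = c(3, 2, 1, 0, 1, 2))),
    "non-positive")
})

test_that("estimator matches an independent least-squares oracle under noise", {
  set.seed(77)
  t <- 0:8
  errs <- replicate(400, {
    mu <- runif(1, 0.1, 0.5)
    a <- 120 * exp(mu * t) * exp(rnorm(9, 0, 0.05))
    tp <- data.frame(track_id = 1, time = t, area_px = a)
    fit <- fit_specific_growth_rate(tp)
    expect_equal(fit$mu, ols_slope(t, log(a)), tolerance = 1e-12)
    fit$mu - mu
  })
  expect_lt(abs(mean(errs)), 0.02)   # bias under 5% multiplicative noise
  expect_lt(mean(abs(errs) > 0.02), 0.05)
})

test_that("spatial QC applies the 35 um neighbour and 55 um edge filters", {
  pitch <- 0.6708
  mk_pts <- function(id, x, y) data.frame(track_id = id, time = 0:5,
                                          area_px = 100, x = x, y = y)
  # colony 50 um from the edge, another with a neighbour at 30 um,
  # and an isolated mid-field colony
  pts <- rbind(mk_pts(1, 50 / pitch, 500),
               mk_pts(2, 500, 500), mk_pts(3, 500 + 30 / pitch, 500),
               mk_pts(4, 900, 900))
  rec <- fit_growth_rates(pts, min_timepoints = 5)
  # make colony 4 truly isolated within a large field
  qc <- compute_spatial_qc(rec, pts, field_px = c(1600, 1600),
                           pixel_pitch = pitch)
  expect_false(qc$included[qc$track_id == 1])
  expect_match(qc$exclusion_reason[qc$track_id == 1], "edge")
  expect_false(qc$included[qc$track_id == 2])
  expect_match(qc$exclusion_reason[qc$track_id == 2], "proximity")
  expect_true(qc$included[qc$track_id == 4])

  # filters commute: flags do not depend on evaluation order
  qc2 <- compute_spatial_qc(rec[rev(seq_len(nrow(rec))), ], pts,
                            field_px = c(1600, 1600), pixel_pitch = pitch)
  m <- match(qc$track_id, qc2$track_id)
  expect_equal(qc$exclusion_reason, qc2$exclusion_reason[m])
})

test_that("reference normalization rescales per well and by controls", {
  rec <- data.frame(mu = c(0.30, 0.20), well = c("A1", "B1"))
  ref <- data.frame(mu = c(0.40, 0.40, 0.50, 0.30), well = c("A1", "A1", "B1", "B1"))
  out <- normalize_rates(rec, ref)
  expect_equal(out$mu_norm, c(0.30 / 0.40, 0.20 / 0.40))

  ctrl <- data.frame(mu = c(0.38, 0.38), well = c("A1", "B1"))
  out2 <- normalize_rates(rec, ref, ctrl)
  gm <- mean(c(0.38 / 0.40, 0.38 / 0.40))
  expect_equal(out2$mu_norm, out$mu_norm / gm)

  rec_bad <- data.frame(mu = 0.3, well = "C7")
  expect_error(normalize_rates(rec_bad, ref), "C7")
})

test_that("distribution summaries count slow growers below half the median", {
  s <- summarize_distribution(c(1, 1, 1, 1, 0.4))
  expect_equal(s$median, 1)
  expect_equal(s$fraction_slow, 0.2)
  expect_equal(summarize_distribution(rep(0.4, 10))$fraction_slow, 0)

  set.seed(5)
  r <- rlnorm(10000, -1, 0.6)
  s2 <- summarize_distribution(r)
  expect_equal(s2$fraction_slow, sum(r < median(r) / 2) / length(r))
  # scale invariance
  expect_equal(summarize_distribution(3.7 * r)$fraction_slow, s2$fraction_slow)
  # cumulative distribution is monotone from 1/n to 1
  expect_true(all(diff(s2$cdf$quantile) > 0))
  expect_equal(range(s2$cdf$quantile), c(1 / 10000, 1))
})

test_that("binned comparisons match exact rank-sum enumeration", {
  # extreme separation, 5 vs 5: p equals the exact extreme-rank probability
  df <- data.frame(v = c(10:14, 1:5), g = c(rep(1, 5), rep(3, 5)))
  out <- bin_and_compare(df, "v", "g", edges = c(0, 2, 4))
  expect_equal(out$p[1], enum_rank_sum_p(df$v[df$g > 2], df$v[df$g < 2]))
  expect_equal(out$p[1], 2 / choose(10, 5), tolerance = 1e-12)

  # permuted labels: exact p is >= 0.05 for most random draws
  set.seed(11)
  hits <- replicate(400, {
    v <- sample(1:100, 16)
    g <- sample(rep(c(1, 3), each = 8))
    suppressWarnings(bin_and_compare(data.frame(v = v, g = g),
                                     "v", "g", c(0, 2, 4))$p[1]) >= 0.05
  })
  expect_gte(mean(hits), 0.94)

  # rank-sum agreement with the oracle across random small untied cases
  for (i in 1:10) {
    x <- sample(1:1000, sample(4:9, 1))
    y <- sample(setdiff(1:1000, x), sample(4:9, 1))
    df2 <- data.frame(v = c(x, y), g = c(rep(1, length(x)), rep(3, length(y))))
    out2 <- bin_and_compare(df2, "v", "g", c(0, 2, 4))
    expect_equal(out2$p[1], enum_rank_sum_p(x, y), tolerance = 1e-12)
  }

  expect_warning(bin_and_compare(data.frame(v = 1:10, g = rep(c(1, 3), 5)),
                                 "v", "g", c(0, 2, 4, 6)), "empty bin")
  expect_error(bin_and_compare(df, "v", "g", c(0, 4)), "2 bins")
})

test_that("area-to-count calibration reports regression and Bland-Altman", {
  a <- seq(100, 1000, by = 100)
  # a perfect proportional relation makes lm's summary grumble, rightly
  cal <- suppressWarnings(calibrate_area_to_count(a, a / 50))
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(cal$slope, 1 / 50, tolerance = 1e-12)
  expect_equal(cal$ba_mean, 0, tolerance = 1e-10)

  set.seed(9)
  counts <- 2 + 0.02 * a + rnorm(10, 0, 1.5)
  cal2 <- calibrate_area_to_count(a, counts)
  expect_lt(abs(cal2$slope - 0.02), 2 * cal2$slope_se)
  expect_lt(cal2$ba_lo, cal2$ba_mean)
  expect_gt(cal2$ba_hi, cal2$ba_mean)

  expect_error(calibrate_area_to_count(c(1, 2), c(1, 2)), "3")
})
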