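test_that("static and well-separated colonies yield clean tracks", {
  # one static colony, 9 frames -> one full track, no termination
  objs <- lapply(0:8, function(t) fake_objects(t, 50, 60, 200))
  tr <- link_frames(objs)
  expect_equal(nrow(tr$tracks), 1)
  expect_equal(tr$tracks$n_points, 9)
  expect_equal(tr$tracks$termination, "none")

  expect_error(link_frames(list(fake_objects(0, 1, 1, 10),
                                fake_objects(0, 1, 1, 10))), "duplicate")

  # rendered series: identity assignment matches the manifest at all frames
  sim <- simulate_timelapse(toy_field(), 0:8)
  tr2 <- link_frames(segment_series(sim))
  truth <- match_tracks_to_truth(tr2, sim$manifest)
  expect_equal(nrow(truth), 3)
  expect_true(all(truth$n_time_matched == truth$n_points))
  expect_true(all(truth$n_points == 9))
})

test_that("edge contact terminates a track after recording the touch", {
  objs <- lapply(0:8, function(t)
    fake_objects(t, 50, 60, 100 * exp(0.3 * t), touches_edge = (t >= 5)))
  tr <- link_frames(objs)
  expect_equal(tr$tracks$n_points, 6)   # frames t = 0..5
  expect_equal(tr$tracks$termination, "touched_edge")
})

test_that("large area drops abort tracking without recording the drop", {
  areas <- c(100, 110, 120, 55, 130, 140)
  objs <- lapply(seq_along(areas), function(k)
    fake_objects(k - 1, 50, 60, areas[k]))
  tr <- link_frames(objs)  # 50% drop at frame 4 vs default 25% abort
  expect_equal(tr$tracks$termination, "area_drop_abort")
  expect_equal(tr$tracks$n_points, 3)
})

test_that("touching neighbours terminate both tracks", {
  lab_apart <- matrix(0L, 30, 30); lab_apart[5:10, 5:10] <- 1L
  lab_apart[5:10, 20:25] <- 2L
  lab_close <- matrix(0L, 30, 30); lab_close[5:10, 5:12] <- 1L
  lab_close[5:10, 14:21] <- 2L     # 1 px gap at cols 13
  mk <- function(t, labs, xs) fake_objects(t, xs, c(7.5, 7.5), c(36, 36),
                                           labels = labs)
  objs <- list(mk(0, lab_apart, c(7.5, 22.5)),
               mk(1, lab_apart, c(7.5, 22.5)),
               mk(2, lab_close, c(8.5, 17.5)))
  tr <- link_frames(objs)
  expect_equal(sort(tr$tracks$termination),
               c("touched_neighbor", "touched_neighbor"))
  expect_true(all(tr$tracks$n_points == 3))  # the touching point is recorded
})

test_that("de-novo objects are absorbed within 0.65 x Feret, else ignored", {
  tracks <- data.frame(track_id = 7L, x = 100, y = 100, feret_px = 40)
  near <- data.frame(label = 1L, x = 100 + 0.5 * 40, y = 100, area_px = 12)
  far <- data.frame(label = 2L, x = 100 + 0.8 * 40, y = 100, area_px = 12)
  both <- rbind(near, far)
  dec <- absorb_de_novo(both, tracks)
  expect_equal(dec$action, c("merged", "ignored"))
  expect_equal(dec$track_id[1], 7L)
  none <- absorb_de_novo(near, tracks[0, ])
  expect_equal(none$action, "ignored")

  # inside link_frames: absorbed area is added to the track and logged
  o1 <- fake_objects(0, 100, 100, 500, feret = 40)
  o2 <- fake_objects(1, c(100, 115), c(100, 100), c(520, 15), feret = 40)
  tr <- link_frames(list(o1, o2))
  expect_equal(nrow(tr$tracks), 1)
  expect_equal(tr$points$area_px[tr$points$time == 1], 535)
  expect_equal(tr$tracks$absorbed_px, 15)

  # ... but a distant newcomer is ignored and reported
  o2b <- fake_objects(1, c(100, 220), c(100, 100), c(520, 15), feret = 40)
  tr2 <- link_frames(list(o1, o2b))
  expect_equal(nrow(tr2$ignored), 1)
  expect_equal(tr2$ignored$area_px, 15)
})

test_that("per-frame pixel accounting balances", {
  sim <- simulate_timelapse(toy_field(), 0:8)
  tr <- link_frames(segment_series(sim))
  acc <- tr$accounting
  expect_true(all(abs(acc$total_object_px -
                        (acc$tracked_px + acc$ignored_px + acc$dropped_px))
                  < 1e-9))
})

test_that("plate shift is recovered from isolated colonies", {
  set.seed(31)
  # wide grid: every colony exceeds the isolation threshold
  g <- expand.grid(x = seq(100, 740, by = 160), y = seq(100, 740, by = 160))
  n <- nrow(g)
  x <- g$x; y <- g$y
  pre <- data.frame(label = 1:n, x = x, y = y, area_px = 300)
  post <- data.frame(label = 1:n, x = x + 5, y = y - 3, area_px = 300)
  est <- estimate_plate_shift(pre, post)
  expect_equal(as.numeric(est), c(5, -3), tolerance = 1e-9)

  est0 <- estimate_plate_shift(pre, pre)
  expect_lt(max(abs(as.numeric(est0))), 0.1)

  # manifest shift (4, 4) + centroid noise sd 0.3 px, isolated colonies:
  # oracle is the mean of the true per-colony displacements
  noisy <- data.frame(label = 1:n, x = x + 4 + rnorm(n, 0, 0.3),
                      y = y + 4 + rnorm(n, 0, 0.3), area_px = 300)
  est2 <- estimate_plate_shift(pre, noisy)
  oracle <- c(mean(noisy$x - x), mean(noisy$y - y))
  expect_lt(max(abs(as.numeric(est2) - c(4, 4))), 0.5)
  expect_equal(as.numeric(est2), oracle, tolerance = 1e-9)

  few <- pre[1:2, ]
  expect_error(estimate_plate_shift(few, post), "isolated")
  crowded <- expand.grid(x = seq(10, 130, length.out = 6),
                         y = seq(10, 40, length.out = 4))  # all close
  crowded$label <- seq_len(nrow(crowded)); crowded$area_px <- 300
  expect_error(estimate_plate_shift(crowded, post), "isolated")
})

test_that("realignment matches survivors back to their pre-shock tracks", {
  objs <- lapply(0:5, function(t)
    fake_objects(t, c(100, 300, 500), c(100, 120, 140),
                 c(200, 300, 400) * exp(0.2 * t)))
  pre_tracks <- link_frames(objs)
  last <- objs[[6]]$table
  shift <- c(6, -4)
  post <- data.frame(label = 1:3, x = last$x + shift[1],
                     y = last$y + shift[2], area_px = last$area_px)
  re <- realign_series(pre_tracks, post, shift)
  expect_equal(nrow(re$pairs), 3)
  expect_equal(re$pairs$post_label[order(re$pairs$track_id)], 1:3)
  expect_lt(max(re$pairs$dist_px), 1e-9)

  # zero shift degenerates to plain nearest-centroid matching
  re0 <- realign_series(pre_tracks, data.frame(label = 1:3, x = last$x,
                                               y = last$y,
                                               area_px = last$area_px),
                        c(0, 0))
  expect_equal(re0$pairs$post_label[order(re0$pairs$track_id)], 1:3)

  # a post object with no pre partner in range is reported unmatched
  orphan <- rbind(post, data.frame(label = 4, x = 700, y = 700, area_px = 50))
  re2 <- realign_series(pre_tracks, orphan, shift)
  expect_equal(re2$unmatched_objects, 4)
})

test_that("no object feeds two tracks in one frame", {
  # two colonies closer than max_displacement: greedy must keep them 1:1
  objs <- lapply(0:8, function(t)
    fake_objects(t, c(100, 112), c(100, 100), c(200, 210)))
  tr <- link_frames(objs)
  pts <- tr$points
  for (tt in unique(pts$time))
    expect_equal(anyDuplicated(pts$track_id[pts$time == tt]), 0)
  expect_equal(nrow(tr$tracks), 2)
  expect_true(all(tr$tracks$n_points == 9))
})
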