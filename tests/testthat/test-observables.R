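test_that("resampling keeps nearest samples to multiples of the interval", {
  tr <- make_track(seq(0, 900, by = 0.01), rep(0, 90001), interval = 0.01)
  tr$t <- seq(0, 900, by = 0.01)   # explicit times
  rs <- resample_track(tr, 3.3)
  expect_equal(n_samples(rs), 274)
  expect_equal(rs$t[1:3], c(0, 3.3, 6.6))
  expect_equal(rs$t[274], 900)
  # identity at the native interval
  small <- bee_track(0:10, 0:10, rep(0, 11), sampling_interval = 1)
  expect_equal(resample_track(small, 1)$t, small$t)
  # two-point tracks pass through unchanged
  two <- bee_track(c(0, 5), c(0, 1), c(0, 1), sampling_interval = 5)
  expect_equal(n_samples(resample_track(two, 10)), 2)
  expect_error(resample_track(small, 0.5), "native")
})

test_that("hovering near a flower collapses to a single point per visit", {
  fl <- matrix(c(100, 0), 1)
  far <- make_track(seq(0, 50, by = 5), rep(20, 11))
  expect_equal(as.data.frame(collapse_near_flowers(far, fl)),
               as.data.frame(far))
  # five consecutive samples within 6 m of the flower become one sample
  x <- c(0, 50, 96, 97, 98, 99, 100, 150, 200)
  hover <- make_track(x, rep(0, 9))
  col <- collapse_near_flowers(hover, fl)
  expect_equal(n_samples(col), 5)
  expect_equal(col$x, c(0, 50, 100, 150, 200))
  expect_equal(col$t[3], 2)   # time of the first sample of the run
  # two separate visits collapse to two points
  x2 <- c(0, 98, 200, 99, 0)
  two <- collapse_near_flowers(make_track(x2, rep(0, 5)), fl)
  expect_equal(two$x, c(0, 100, 200, 100, 0))
})

test_that("loops span from last sample inside the disc to first back inside", {
  # out and back once
  x <- c(0, 5, 20, 40, 20, 5, 0)
  tr <- make_track(x, rep(0, 7))
  loops <- extract_loops(tr, nest_radius = 13)
  expect_length(loops, 1)
  expect_equal(loops[[1]]$x, c(5, 20, 40, 20, 5))
  expect_false(loops[[1]]$censored)
  # never leaves the disc
  expect_length(extract_loops(make_track(c(0, 5, 9, 3), rep(0, 4)),
                              nest_radius = 13), 0)
  # excursion open at the end of the track is censored
  open_tr <- make_track(c(0, 5, 20, 40), rep(0, 4))
  open_loops <- extract_loops(open_tr, nest_radius = 13)
  expect_length(open_loops, 1)
  expect_true(open_loops[[1]]$censored)
})

test_that("extraction partitions a track and matches the simulator's log", {
  p <- default_params()
  set.seed(201)
  tr <- simulate_trip(p, duration = 900)
  loops <- extract_loops(tr, nest = c(0, 0), nest_radius = p$nest_radius)
  # partition: interior samples of loops cover each excursion sample once
  d <- sqrt(tr$x^2 + tr$y^2)
  n_out <- sum(d > p$nest_radius)
  interior <- sum(vapply(loops, function(l) n_samples(l) - 2L, integer(1)) +
                    vapply(loops, function(l) isTRUE(l$censored), logical(1)))
  expect_equal(interior, n_out)
  # loops that close in the return phase correspond one-to-one to logged
  # nest entries reached from outside the disc; entries whose switch fired
  # while the bee had already drifted back inside are geometrically
  # invisible to extraction
  closed <- Filter(function(l) !l$censored, loops)
  end_phase <- vapply(closed, function(l) l$phase[n_samples(l)], integer(1))
  end_t <- vapply(closed, function(l) l$t[n_samples(l)], numeric(1))
  idx <- match(round(tr$loop_entries, 6), round(tr$t, 6))
  from_outside <- d[idx - 1L] > p$nest_radius
  expect_equal(sum(end_phase == 1L), sum(from_outside))
  expect_true(all(round(tr$loop_entries[from_outside], 6) %in%
                    round(end_t, 6)))
})

test_that("length and extension follow hand geometry and scale linearly", {
  sq <- make_loop(c(0, 0, 100, 100, 0), c(0, 100, 100, 0, 0))
  expect_equal(loop_length(sq), 400)
  expect_equal(loop_extension(sq), 100 * sqrt(2))
  expect_equal(loop_length(make_loop(c(0, 3), c(0, 4))), 5)
  sq2 <- make_loop(2 * c(0, 0, 100, 100, 0), 2 * c(0, 100, 100, 0, 0))
  expect_equal(loop_length(sq2), 2 * loop_length(sq))
  expect_equal(loop_extension(sq2), 2 * loop_extension(sq))
})

test_that("self-intersection counting agrees with the brute-force oracle", {
  convex <- make_loop(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0))
  expect_equal(count_self_intersections(convex), 0)
  eight <- make_loop(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_equal(count_self_intersections(eight), 1)
  set.seed(202)
  for (k in 1:50) {
    n <- sample(10:60, 1)
    x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
    lp <- make_loop(x, y)
    expect_equal(count_self_intersections(lp),
                 oracle_count_intersections(x, y))
  }
})

test_that("re-departures scan the three-point approach-then-recede pattern", {
  outback <- make_loop(c(0, 10, 20, 30, 20, 10, 0), rep(0, 7))
  expect_equal(count_redepartures(outback), 0)
  seq5 <- make_loop(c(50, 40, 45, 30, 35), rep(0, 5))
  expect_equal(count_redepartures(seq5), 2)
  # the pattern is a strict local minimum of the distance profile, which is
  # preserved by reversing the loop
  set.seed(207)
  for (k in 1:10) {
    d <- abs(cumsum(rnorm(20))) + 1
    fwd <- make_loop(d, rep(0, 20))
    bwd <- make_loop(rev(d), rep(0, 20))
    expect_equal(count_redepartures(fwd), count_redepartures(bwd))
  }
})

test_that("per-100m rates are integer-binned and zero counts give zero rates", {
  tri <- make_loop(c(0, 100, 100, 0), c(0, 0, 100, 0))   # length 341.4 m
  ob <- loop_observables(tri)
  expect_equal(ob$intersections_per_100m, 0L)
  expect_equal(ob$redepartures_per_100m, 0L)
  # three crossings over ~300 m -> 1 per 100 m
  set.seed(203)
  repeat {
    x <- cumsum(rnorm(40, sd = 5)); y <- cumsum(rnorm(40, sd = 5))
    if (oracle_count_intersections(x, y) >= 1) break
  }
  lp <- make_loop(x, y)
  len <- loop_length(lp)
  expect_equal(loop_observables(lp)$intersections_per_100m,
               as.integer(round(oracle_count_intersections(x, y) /
                                  (len / 100))))
})

test_that("observables are invariant under rotation and translation", {
  p <- default_params()
  set.seed(204)
  loop <- simulate_loop(p, record_interval = 3.3)
  ob <- loop_observables(loop, nest = c(0, 0))
  a <- 1.2; shift <- c(300, -150)
  rx <- cos(a) * loop$x - sin(a) * loop$y + shift[1]
  ry <- sin(a) * loop$x + cos(a) * loop$y + shift[2]
  moved <- make_loop(rx, ry, interval = 3.3, nest = shift)
  ob2 <- loop_observables(moved, nest = shift)
  expect_equal(ob2$loop_length, ob$loop_length, tolerance = 1e-9)
  expect_equal(ob2$loop_extension, ob$loop_extension, tolerance = 1e-9)
  expect_equal(ob2$intersections_per_100m, ob$intersections_per_100m)
  expect_equal(ob2$redepartures_per_100m, ob$redepartures_per_100m)
})

test_that("resampling can only shorten a loop (triangle inequality)", {
  p <- default_params()
  set.seed(205)
  for (k in 1:5) {
    loop <- simulate_loop(p)
    expect_lte(loop_length(resample_track(loop, 3.3)), loop_length(loop))
    # out-and-back geometry bounds the extension by half the length plus
    # the width of the nest disc
    expect_lte(loop_extension(loop), loop_length(loop) / 2 + p$nest_radius)
  }
})

test_that("loop tables round-trip through CSV with identical observables", {
  p <- default_params()
  set.seed(206)
  loops <- replicate(20, simulate_loop(p, record_interval = 3.3),
                     simplify = FALSE)
  tab <- loops_table(loops, interval = 3.3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_loop_table(loops, path, interval = 3.3)
  back <- read.csv(path)
  expect_equal(back$length_m, tab$length_m, tolerance = 1e-8)
  expect_equal(back$intersections_per100m, tab$intersections_per100m)
  # a single loop round-trips through the track CSV too
  tp <- withr::local_tempfile(fileext = ".csv")
  write_track(loops[[1]], tp)
  tr2 <- read_track(tp, sampling_interval = 3.3)
  lp2 <- beeloop:::as_bee_loop(tr2)
  expect_equal(loop_observables(lp2), loop_observables(loops[[1]]),
               tolerance = 1e-6)
})
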