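test_that("schedules conserve duration, alternate labels and are seeded", {
  sch <- generate_schedule(600, mean_fly_bout = 120, mean_rest_bout = 120,
                           seed = 1)
  expect_equal(sum(sch$end - sch$start), 600)
  expect_equal(sch$start[-1], sch$end[-nrow(sch)])   # contiguous
  expect_true(all(sch$end - sch$start > 0))
  expect_true(all(rle(sch$label)$lengths == 1))      # strict alternation
  expect_identical(sch, generate_schedule(600, 120, 120, seed = 1))
  expect_false(identical(sch$end,
                         generate_schedule(600, 120, 120, seed = 2)$end))
  expect_error(generate_schedule(-5), "positive")
})

test_that("an effectively infinite flying mean yields a single flying bout", {
  sch <- generate_schedule(600, mean_fly_bout = 1e9, mean_rest_bout = 120,
                           seed = 3, first = "flying")
  expect_equal(nrow(sch), 1L)
  expect_equal(sch$label, "flying")
  expect_equal(sch$end, 600)
})

test_that("noise-free acceleration is gravity during rest, a flap sinusoid in flight", {
  rest <- manual_schedule("non_flying", 10)
  a <- synth_acceleration(rest, noise_sd = 0, seed = 1)
  expect_equal(nrow(a), 250L)
  expect_equal(unique(a$ax), 0)
  expect_equal(unique(a$ay), 0)
  expect_equal(unique(a$az), 1)

  fly <- manual_schedule("flying", 10)
  b <- synth_acceleration(fly, flap_amp = 0.5, flap_freq = 3, noise_sd = 0,
                          seed = 1)
  # peak-to-peak of the heave sinusoid at the sampled phases
  expected_p2p <- 2 * 0.5 * max(abs(sin(2 * pi * 3 * b$t)))
  expect_equal(max(b$az) - min(b$az), expected_p2p, tolerance = 1e-12)
  expect_equal(expected_p2p, 1.0, tolerance = 3e-3)
  expect_error(synth_acceleration(fly, flap_freq = 13), "Nyquist")
})

test_that("the flight spectrum peaks at the flapping frequency (DFT oracle)", {
  fly <- manual_schedule("flying", 40)
  a <- synth_acceleration(fly, flap_freq = 3, flap_amp = 0.5,
                          noise_sd = 0.05, seed = 11)
  z <- a$az - mean(a$az)
  spec <- Mod(stats::fft(z))[seq_len(length(z) / 2)]
  freqs <- (seq_along(spec) - 1) * 25 / length(z)
  expect_lt(abs(freqs[which.max(spec)] - 3), 25 / length(z) + 1e-9)
})

test_that("GPS is stationary at the colony during rest and integrates speed in flight", {
  rest <- manual_schedule("non_flying", 60)
  g <- synth_gps(rest, fix_dropout_p = 0, seed = 1)
  expect_equal(unique(g$lat), 40.539)
  expect_equal(unique(g$lon), 141.558)
  expect_equal(unique(g$speed), 0)
  expect_true(all(g$fix3d))

  fly <- manual_schedule("flying", 300)
  g2 <- synth_gps(fly, fly_speed = 10, fix_dropout_p = 0, seed = 5)
  # 299 s of travel at 10 m/s from the colony (haversine oracle)
  d <- haversine_km(c(g2$lat[1], g2$lon[1]), c(g2$lat[300], g2$lon[300]))
  expect_equal(d, 2.99, tolerance = 0.05 * 2.99)
  skip_if_not_installed("geosphere")
  d_ref <- geosphere::distHaversine(c(g2$lon[1], g2$lat[1]),
                                    c(g2$lon[300], g2$lat[300]),
                                    r = 6371000) / 1000
  expect_equal(d, d_ref, tolerance = 1e-9)
})

test_that("reported ground speed matches positional displacement within 5%", {
  fly <- manual_schedule("flying", 120)
  g <- synth_gps(fly, fly_speed = 12, fix_dropout_p = 0, seed = 9)
  step_km <- haversine_km(cbind(g$lat[-nrow(g)], g$lon[-nrow(g)]),
                          cbind(g$lat[-1], g$lon[-1]))
  expect_true(all(abs(step_km * 1000 - 12) / 12 < 0.05))
})

test_that("fix dropouts occur at the configured rate", {
  sch <- manual_schedule("flying", 2000)
  g <- synth_gps(sch, fix_dropout_p = 0.2, seed = 21)
  expect_gt(mean(!g$fix3d), 0.15)
  expect_lt(mean(!g$fix3d), 0.25)
})

test_that("mask-ratio stream honours jitter, injections and clipping", {
  sch <- manual_schedule("non_flying", 120)
  m0 <- synth_mask_ratio(sch, jitter_sd = 0, seed = 1)
  expect_equal(nrow(m0), 120 * 30)
  expect_equal(length(unique(m0$mpr)), 1L)
  expect_true(all(diff(m0$mpr) == 0))

  inj <- response_injection(60, c(ad_mpr = 0.1), decay = 10)
  m1 <- synth_mask_ratio(sch, jitter_sd = 0.02, injections = list(inj),
                         seed = 2)
  d <- abs(diff(m1$mpr))
  td <- m1$t[-1]
  expect_gt(mean(d[td > 60 & td <= 65]), mean(d[td > 55 & td <= 60]))

  m2 <- synth_mask_ratio(sch, base_mpr = 1, jitter_sd = 0.05, seed = 3)
  expect_true(all(m2$mpr <= 1))
  expect_gt(mean(m2$mpr == 1), 0.3)   # positive jitter always clipped
  expect_error(synth_mask_ratio(sch, base_mpr = 1.2), "\\[0, 1\\]")
})

test_that("bundles are bit-identical under a repeated seed and span one time range", {
  b1 <- synth_bundle(120, seed = 77)
  b2 <- synth_bundle(120, seed = 77)
  expect_identical(b1, b2)
  expect_equal(nrow(b1$accel), 120 * 25)
  expect_equal(nrow(b1$gps), 120)
  expect_equal(nrow(b1$mask), 120 * 30)
  expect_equal(range(b1$accel$t), c(0, 120 - 1 / 25))
  expect_true(all(b1$mask$mpr >= 0 & b1$mask$mpr <= 1))
  expect_true(all(abs(b1$gps$lat) <= 90 & abs(b1$gps$lon) <= 180))
  expect_equal(diff(b1$accel$t)[1], 1 / 25)
})

test_that("per-second heave variance separates the behaviour classes", {
  # 100 seeded bundles at the study noise level; seconds lying wholly
  # inside one bout must show disjoint flying vs non-flying heave variance.
  overlap <- 0L
  for (s in 1:100) {
    b <- synth_bundle(60, seed = 4000 + s, include_mask = FALSE,
                      mean_fly_bout = 20, mean_rest_bout = 20,
                      flap_amp = 0.5, noise_sd = 0.05)
    fw <- accel_features(b$accel)
    lab0 <- schedule_label(b$schedule, fw$t_start)
    lab1 <- schedule_label(b$schedule, fw$t_start + 1 - 1e-9)
    pure <- lab0 == lab1
    v <- fw$features[, "sd_z"]^2
    fly <- v[pure & lab0 == "flying"]
    rest <- v[pure & lab0 == "non_flying"]
    if (length(fly) && length(rest) && min(fly) <= max(rest))
      overlap <- overlap + 1L
  }
  expect_equal(overlap, 0L)
})
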