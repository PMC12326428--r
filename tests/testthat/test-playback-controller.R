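test_that("haversine matches the spherical oracle and is symmetric", {
  expect_equal(haversine_km(c(10, 20), c(10, 20)), 0)
  expect_equal(haversine_km(c(0, 0), c(1, 0)), 111.195, tolerance = 1e-5)
  # spherical law of cosines oracle
  slc <- function(p1, p2) {
    f1 <- p1[1] * pi / 180; f2 <- p2[1] * pi / 180
    dl <- (p2[2] - p1[2]) * pi / 180
    6371 * acos(pmin(1, sin(f1) * sin(f2) + cos(f1) * cos(f2) * cos(dl)))
  }
  set.seed(12)
  for (i in 1:100) {
    p1 <- c(runif(1, -80, 80), runif(1, -179, 179))
    p2 <- c(runif(1, -80, 80), runif(1, -179, 179))
    expect_equal(haversine_km(p1, p2), haversine_km(p2, p1))
    expect_equal(haversine_km(p1, p2), slc(p1, p2), tolerance = 1e-6)
  }
  expect_error(haversine_km(c(95, 0), c(0, 0)), "out of range")
})

test_that("standby eligibility needs a full ring of 3D fixes outside the geofence", {
  cfg <- controller_config(colony = c(40, 141))
  far <- data.frame(lat = rep(40 + 2 / 111.1949, 10), lon = 141,
                    fix3d = TRUE)
  expect_true(standby_eligible(far, cfg))
  one_unfixed <- far
  one_unfixed$fix3d[4] <- FALSE
  expect_false(standby_eligible(one_unfixed, cfg))
  expect_false(standby_eligible(far[1:9, ], cfg))   # under-full, not error
  near <- far
  near$lat[7] <- 40 + 0.99 / 111.1949
  expect_lt(haversine_km(c(near$lat[7], near$lon[7]), cfg$colony), 1)
  expect_false(standby_eligible(near, cfg))
})

test_that("continuous eligible flight plays back exactly pre_record_s after video start", {
  sch <- manual_schedule("flying", 400)
  b <- bundle_from_schedule(sch, seed = 2, fly_speed = 10.5)
  run <- run_controller(b, model = NULL, seed = 3)
  ev <- run$events
  # hand-traced: HIGH at t=4 (5 consecutive flying ticks 0..4); ring holds
  # fixes from t=5 on; 10.5 m/s crosses 1 km at t=96 (1.008 km), so the
  # ring 96..105 first qualifies at t=105; the 5-s standby dwell puts
  # VIDEO_START at 110 and playback at 110 + 60.
  expect_equal(ev$t[ev$kind == "GPS_MODE_HIGH"], 4)
  expect_equal(ev$t[ev$kind == "STANDBY_ENTER"], 105)
  expect_equal(ev$t[ev$kind == "VIDEO_START"], 110)
  expect_equal(ev$t[ev$kind == "PLAYBACK_START"], 170)
  expect_equal(ev$t[ev$kind == "PLAYBACK_END"], 171)
  expect_equal(ev$t[ev$kind == "VIDEO_STOP"], 230)
  s <- run$sessions
  expect_equal(nrow(s), 1L)
  expect_false(s$cancelled)
  expect_equal(s$playback_t - s$video_start, 60)
  expect_true(s$ring_all_fix3d)
  expect_gt(s$ring_min_km, 1)
  expect_true(s$audio %in% c("predator", "noise"))
})

test_that("landing during pre-record cancels the session without playback", {
  # flying long enough to reach pre-record (video at 110), lands at 125
  sch <- manual_schedule(c("flying", "non_flying", "flying"),
                         c(125, 30, 245))
  b <- bundle_from_schedule(sch, seed = 4, fly_speed = 10.5)
  run <- run_controller(b, model = NULL, seed = 5)
  ev <- run$events
  expect_equal(ev$t[ev$kind == "VIDEO_START"][1], 110)
  expect_true("SESSION_CANCELLED" %in% ev$kind)
  s1 <- run$sessions[1, ]
  expect_true(s1$cancelled)
  expect_true(is.na(s1$playback_t))
  # cancellation fires once 5 consecutive non-flying seconds accumulate
  expect_equal(s1$end_t, 129)
})

test_that("the refractory lockout suppresses a second nearby opportunity", {
  # two flights; the second starts 300 s after the first session ends and
  # must therefore be ignored (600 s lockout)
  sch <- manual_schedule(c("flying", "non_flying", "flying", "non_flying"),
                         c(240, 60, 400, 500))
  b <- bundle_from_schedule(sch, seed = 6)
  run <- run_controller(b, model = NULL, seed = 7)
  s <- run$sessions
  expect_equal(nrow(s), 1L)   # second flight falls inside the lockout
  expect_true("REFRACTORY_END" %in% run$events$kind)
})

test_that("three refractory-spaced flights yield three playback sessions", {
  sch <- manual_schedule(
    c("flying", "non_flying", "flying", "non_flying", "flying", "non_flying"),
    c(400, 700, 400, 700, 400, 100))
  b <- bundle_from_schedule(sch, seed = 8)
  run <- run_controller(b, model = NULL, seed = 9)
  s <- run$sessions
  expect_equal(nrow(s), 3L)
  expect_true(all(!s$cancelled))
  expect_equal(sum(run$events$kind == "PLAYBACK_START"), 3L)
  expect_equal(s$playback_t - s$video_start, rep(60, 3))
  expect_true(all(diff(s$video_start) >= 600))
})

test_that("an all-resting bundle produces no events and no sessions", {
  sch <- manual_schedule("non_flying", 600)
  b <- bundle_from_schedule(sch, seed = 10)
  run <- run_controller(b, model = NULL, seed = 11)
  expect_equal(nrow(run$sessions), 0L)
  expect_equal(nrow(run$events), 0L)
})

test_that("audio draws are seeded and uniform over the stimulus set", {
  sch <- manual_schedule(
    c("flying", "non_flying", "flying", "non_flying", "flying", "non_flying"),
    c(400, 700, 400, 700, 400, 100))
  b <- bundle_from_schedule(sch, seed = 8)
  r1 <- run_controller(b, model = NULL, seed = 13)
  r2 <- run_controller(b, model = NULL, seed = 13)
  expect_identical(r1$sessions$audio, r2$sessions$audio)
  draws <- draw_audio(2000, seed = 99)
  expect_identical(draws, draw_audio(2000, seed = 99))
  expect_gt(mean(draws == "predator"), 0.45)
  expect_lt(mean(draws == "predator"), 0.55)
})

test_that("out-of-order ticks are rejected", {
  cfg <- controller_config()
  st <- playbacklogger:::controller_init(cfg)
  st <- playbacklogger:::controller_step(st, "flying", NULL, 5, cfg)$state
  expect_error(playbacklogger:::controller_step(st, "flying", NULL, 4, cfg),
               "out-of-order")
})
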