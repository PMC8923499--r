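test_that("array generation honors nominal spacing and rejects tiny arrays", {
  cfg <- scenario_config()
  arr <- gen_array(cfg, seed = 1)
  expect_equal(nrow(arr), 13)
  d <- sqrt(diff(arr$x)^2 + diff(arr$y)^2)
  expect_equal(d, rep(70, 12))
  expect_equal(sum(arr$role == "reference"), 1)

  arr3 <- gen_array(scenario_config(n_receivers = 3), seed = 1)
  expect_equal(nrow(arr3), 3)
  expect_error(scenario_config(n_receivers = 2))
})

test_that("placement jitter perturbs spacings and is seed-reproducible", {
  cfg <- scenario_config(array_jitter_sd = 8)
  a1 <- gen_array(cfg, seed = 7)
  a2 <- gen_array(cfg, seed = 7)
  a3 <- gen_array(cfg, seed = 8)
  expect_identical(a1, a2)
  expect_false(identical(a1$x, a3$x))
  d <- sqrt(diff(a1$x)^2 + diff(a1$y)^2)
  iqr <- diff(stats::quantile(d, c(0.25, 0.75)))
  expect_gt(iqr, 0) # jitter spreads adjacent distances
  expect_true(all(abs(d - 70) < 8 * 6))
})

test_that("degenerate profiles give a uniform field; log-law is monotone", {
  cfg <- scenario_config(channel = list(peak_speed = 0.5))
  f <- gen_field(cfg, duration = 600, lateral_profile = "uniform",
                 vertical_profile = "uniform")
  pts <- expand.grid(x = c(10, 500, 990), y = c(1, 25, 49), t = c(0, 600))
  uv <- extract_velocity(f, pts$x, pts$y, pts$t, "top1m")
  expect_equal(uv$u, rep(0.5, nrow(pts)))
  expect_equal(uv$v, rep(0, nrow(pts)))

  flog <- gen_field(cfg, duration = 600, lateral_profile = "uniform")
  prof <- rheotrack:::.interp_profiles(flog, 500, 25, 300)
  expect_true(all(diff(prof$u[1, ]) >= 0))
})

test_that("cross-channel mean of the parabolic lateral profile matches its analytic mean", {
  cfg <- scenario_config()
  f <- gen_field(cfg, duration = 600, vertical_profile = "uniform")
  y <- seq(0, 50, by = 0.25)
  u <- extract_velocity(f, rep(500, length(y)), y, 300, "full")$u
  # trapezoid mean of u(y); analytic mean of 4*s*(1-s) on [0,1] is 2/3
  num <- sum(diff(y) * (head(u, -1) + u[-1]) / 2) / 50
  expect_lt(abs(num - 0.5 * 2 / 3) / (0.5 * 2 / 3), 0.01)
})

test_that("passive fish drift with the water; behaviors add the prescribed vector", {
  f <- uniform_field(u = 0.4, v = 0, L = 2000, duration = 4000)
  base <- list(label = "passive", fraction = 1, swim_speed = 0, diel = FALSE)
  mk <- function(label, speed) {
    scenario_config(behaviors = data.frame(label = label, fraction = 1,
                                           swim_speed = speed, diel = FALSE))
  }
  tr_p <- simulate_fish(f, mk("passive", 0), n_fish = 2, release_span = 0,
                        t_max = 4000, seed = 1)
  expect_true(all(tr_p$swim_u == 0 & tr_p$swim_v == 0))
  one <- tr_p[tr_p$tag_id == "F001", ]
  expect_equal(diff(range(one$x)), 0.4 * diff(range(one$t)), tolerance = 1e-9)
  expect_equal(diff(range(one$y)), 0, tolerance = 1e-9)

  tr_r <- simulate_fish(f, mk("positive_rheotaxis", 0.1), n_fish = 1,
                        release_span = 0, t_max = 4000, seed = 1)
  gs <- diff(range(tr_r$x)) / diff(range(tr_r$t))
  expect_equal(gs, 0.3, tolerance = 1e-9)

  tr_l <- simulate_fish(f, mk("lateral", 0.09), n_fish = 1,
                        release_span = 0, t_max = 4000, seed = 1)
  lat_rate <- abs(diff(range(tr_l$y))) / diff(range(tr_l$t))
  expect_equal(lat_rate, 0.09, tolerance = 1e-9)
})

test_that("noise-free detections reproduce exact propagation and additive offsets", {
  cfg <- scenario_config(arrival_noise_sd = 0, detection_prob = 1,
                         corrupt_frac = 0, pri_jitter_sd = 0)
  arr <- gen_array(cfg, seed = 1)
  sim <- simulate_detections(NULL, arr, cfg, t_span = c(0, 600), seed = 2)
  truth <- sim$truth$arrivals
  pos <- stats::setNames(split(arr[, c("x", "y", "z")], seq_len(nrow(arr))),
                         arr$id)
  det <- dplyr::left_join(sim$detections, truth[, c("det_id", "ping_id")],
                          by = "det_id")
  emis <- sim$truth$emissions
  ei <- match(det$ping_id, emis$ping_id)
  ri <- match(det$receiver_id, arr$id)
  d <- sqrt((emis$x[ei] - arr$x[ri])^2 + (emis$y[ei] - arr$y[ri])^2 +
              (emis$z[ei] - arr$z[ri])^2)
  lag <- det$raw_time - d / cfg$sound_speed
  spread <- tapply(lag, det$ping_id, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-9)

  # constant 0.5 s offset on one receiver shifts exactly its raw times
  dr <- dplyr::bind_rows(lapply(arr$id, function(id) tibble::tibble(
    receiver_id = id, knot_time = c(0, 600),
    offset = if (id == "R05") 0.5 else 0)))
  sim2 <- simulate_detections(NULL, arr, cfg, t_span = c(0, 600),
                              drifts = dr, seed = 2)
  shift <- sim2$detections$raw_time - sim$detections$raw_time
  is_r05 <- sim$detections$receiver_id == "R05"
  expect_equal(unique(shift[is_r05]), 0.5)
  expect_equal(unique(shift[!is_r05]), 0)
})

test_that("corrupted-detection count matches the truth record and is reproducible", {
  cfg <- scenario_config(corrupt_frac = 0.001)
  arr <- gen_array(cfg, seed = 1)
  sim <- simulate_detections(NULL, arr, cfg, t_span = c(0, 7200), seed = 9)
  n_corr <- length(sim$truth$corrupted_ids)
  expect_gt(nrow(sim$detections), 15000)
  # brute-force: corrupted rows are exactly those whose raw_time exceeds
  # the direct-path arrival by more than the noise scale
  tr <- sim$truth$arrivals
  delay <- sim$detections$raw_time - tr$t_arrival[match(sim$detections$det_id,
                                                        tr$det_id)]
  flagged <- sim$detections$det_id[delay > 0.004]
  expect_setequal(flagged, sim$truth$corrupted_ids)
  expect_equal(n_corr, length(flagged))

  sim_b <- simulate_detections(NULL, arr, cfg, t_span = c(0, 7200), seed = 9)
  expect_identical(sim$detections, sim_b$detections)
})

test_that("gauge discharge equals the analytic flux", {
  cfg <- scenario_config(channel = list(width = 50, depth = 4,
                                        peak_speed = 0.5))
  f <- gen_field(cfg, duration = 1200, lateral_profile = "uniform",
                 vertical_profile = "uniform")
  g <- gen_gauges(f, cfg, times = c(0, 600))
  expect_equal(g$Q, rep(0.5 * 50 * 4, 2), tolerance = 1e-9)

  f0 <- gen_field(scenario_config(channel = list(peak_speed = 0)),
                  duration = 1200)
  g0 <- gen_gauges(f0, scenario_config(), times = c(0, 600))
  expect_equal(g0$Q, c(0, 0))

  cfgt <- scenario_config(channel = list(width = 50, depth = 4,
                                         peak_speed = 0.5,
                                         tidal_amplitude = 0.2,
                                         tidal_period = 3600))
  ft <- gen_field(cfgt, duration = 3600, lateral_profile = "uniform",
                  vertical_profile = "uniform")
  gt <- gen_gauges(ft, cfgt, times = ft$t)
  expected <- (0.5 + 0.2 * sin(2 * pi * ft$t / 3600)) * 200
  expect_equal(gt$Q, expected, tolerance = 1e-6)
})

test_that("simulated ground velocity minus water velocity recovers the true swim velocity", {
  cfg <- scenario_config(behaviors = data.frame(
    label = "positive_rheotaxis", fraction = 1, swim_speed = 0.1,
    diel = FALSE))
  f <- gen_field(cfg, duration = 3600)
  tr <- simulate_fish(f, cfg, n_fish = 2, release_span = 0, t_max = 3600,
                      seed = 4)
  for (tag in unique(tr$tag_id)) {
    one <- tr[tr$tag_id == tag, ]
    n <- nrow(one)
    uo_u <- diff(one$x) / diff(one$t)
    uw <- extract_velocity(f, one$x[-n], one$y[-n], one$t[-n], "full",
                           strict = FALSE)
    err <- (uo_u - uw$u) - one$swim_u[-n]
    expect_lt(stats::median(abs(err), na.rm = TRUE), 0.005) # O(dt) Euler error
  }
})

test_that("a scenario read from YAML matches its constructor equivalent", {
  cfg <- read_scenario(system.file("extdata", "example_scenario.yaml",
                                   package = "rheotrack"))
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$n_receivers, 13)
  expect_equal(cfg$pri, 5)
  expect_equal(cfg$channel$depth, 4)
  expect_equal(sum(cfg$behaviors$fraction), 1)
  expect_equal(cfg$fork_length_mm, c(76.6, 3))
})
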