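mk_records <- function(tags, segs_per_tag, vranges = "full", u_long = 0,
                       v_lat = 0) {
  tidyr::expand_grid(tag_id = tags, seg = seq_len(segs_per_tag),
                     vrange = vranges) |>
    dplyr::mutate(u_long = u_long, v_lat = v_lat, frame_defined = TRUE)
}

test_that("segment weights equalize individuals and absorb the replicate factor", {
  r1 <- segment_weights(mk_records("A", 4))
  expect_equal(r1$weight, rep(0.25, 4))

  r2 <- segment_weights(dplyr::bind_rows(mk_records("A", 2),
                                         mk_records("B", 8)))
  tot <- r2 |> dplyr::group_by(tag_id) |>
    dplyr::summarise(w = sum(weight))
  expect_equal(tot$w, c(1, 1))

  r3 <- segment_weights(mk_records(c("A", "B"), 5, vranges = vrange_levels()))
  tot3 <- r3 |> dplyr::group_by(tag_id) |> dplyr::summarise(w = sum(weight))
  expect_equal(tot3$w, c(1, 1))
})

test_that("the weighted median follows the cumulative-weight definition", {
  expect_equal(weighted_median(c(1, 2, 3)), 2)
  expect_equal(weighted_median(c(0, 10), c(0.75, 0.25)), 0)
  expect_equal(weighted_median(c(10, 0), c(0.25, 0.75)), 0)
  # equal weights reduce to the ordinary median for odd n
  set.seed(4)
  for (i in 1:10) {
    v <- rnorm(2 * sample(3:20, 1) + 1)
    expect_equal(weighted_median(v), stats::median(v))
  }
})

test_that("bootstrap CIs bracket the weighted median and cover the truth", {
  set.seed(10)
  v <- rnorm(400, mean = -0.1, sd = 0.05)
  out <- weighted_median_ci(v, runif(400, 0.5, 1.5), n_boot = 400, seed = 2)
  expect_lte(out$ci[1], out$median + 1e-9)
  expect_gte(out$ci[2], out$median - 1e-9)

  hits <- 0
  for (r in 1:200) {
    set.seed(1000 + r)
    x <- rnorm(500)
    ci <- weighted_median_ci(x, 1, n_boot = 200, seed = r)$ci
    hits <- hits + (ci[1] <= 0 && 0 <= ci[2])
  }
  expect_gte(hits / 200, 0.85)
})

test_that("the weighted KDE is a proper density and reduces to the unweighted case", {
  set.seed(6)
  v <- c(rnorm(150, -0.1, 0.05), rnorm(80, 0.1, 0.05))
  k <- weighted_kde(v)
  expect_true(all(k$density >= 0))
  dx <- diff(k$x[1:2])
  expect_equal(sum(k$density) * dx, 1, tolerance = 1e-3)

  kw <- weighted_kde(v, weights = rep(2, length(v)), bandwidth = 0.04)
  ku <- weighted_kde(v, weights = 1, bandwidth = 0.04)
  expect_equal(kw$density, ku$density, tolerance = 1e-12)

  # single location with fixed bandwidth is the kernel centered there
  ks <- weighted_kde(rep(1.5, 10), bandwidth = 0.2)
  expect_equal(ks$density, dnorm(ks$x, 1.5, 0.2), tolerance = 1e-12)

  # symmetric data give a symmetric density
  vs <- c(-2, -1, 1, 2)
  ksym <- weighted_kde(vs, bandwidth = 0.5, n_grid = 401)
  expect_equal(ksym$density, rev(ksym$density), tolerance = 1e-6)

  # mode location matches a brute-force dense-grid evaluation
  dense <- seq(min(v) - 0.2, max(v) + 0.2, length.out = 8001)
  brute <- vapply(dense, function(g)
    mean(dnorm(g, v, 0.04)), numeric(1))
  k2 <- weighted_kde(v, bandwidth = 0.04, n_grid = 2001)
  expect_lt(abs(k2$x[which.max(k2$density)] - dense[which.max(brute)]),
            0.005)

  # cross-check against the fft-binned estimator in stats::density
  d <- stats::density(v, bw = 0.04, n = 512)
  kd <- weighted_kde(v, bandwidth = 0.04)
  at <- seq(-0.2, 0.2, by = 0.01)
  expect_equal(approx(kd$x, kd$density, at)$y,
               approx(d$x, d$y, at)$y, tolerance = 1e-3)
})

test_that("rheotaxis occurrence is the weighted negative-u_long fraction", {
  rec <- tibble::tibble(u_long = c(-0.1, 0.1), weight = c(0.75, 0.25))
  expect_equal(as.numeric(rheotaxis_fraction(rec)), 0.75)
  rec2 <- tibble::tibble(u_long = -runif(20), weight = runif(20))
  expect_equal(as.numeric(rheotaxis_fraction(rec2)), 1)
  set.seed(12)
  rec3 <- tibble::tibble(u_long = rnorm(200), weight = runif(200))
  oracle <- sum(rec3$weight * (rec3$u_long < 0)) / sum(rec3$weight)
  expect_equal(as.numeric(rheotaxis_fraction(rec3)), oracle)
  expect_equal(attr(rheotaxis_fraction(rec3), "unweighted"),
               mean(rec3$u_long < 0))
})

test_that("stride-1 speeds agree with the segment pathway and are stride-invariant when noiseless", {
  f <- uniform_field(u = 0.4)
  fx <- tibble::tibble(tag_id = "A", t = seq(0, 200, by = 5),
                       x = 100 + 0.3 * seq(0, 200, by = 5), y = 25)
  s1 <- stride_speeds(fx, f, "full", stride = 1)
  rec <- swim_records(make_segments(fx), f, vranges = "full")
  expect_equal(sort(s1), sort(sqrt(rec$us_u^2 + rec$us_v^2)))
  s4 <- stride_speeds(fx, f, "full", stride = 4)
  expect_equal(unique(round(c(s1, s4), 12)), 0.1)
})

test_that("positional noise inflates speeds and longer strides deflate the bias", {
  f <- uniform_field(u = 0.4, L = 3000)
  tt <- seq(0, 600, by = 5)
  base <- tibble::tibble(tag_id = "A", t = tt, x = 100 + 0.4 * tt, y = 25)
  set.seed(17)
  meds <- sapply(c(0, 0.7, 1.4), function(s) {
    noisy <- dplyr::mutate(base, x = x + rnorm(length(tt), sd = s),
                           y = y + rnorm(length(tt), sd = s))
    stats::median(stride_speeds(noisy, f, "full", stride = 1))
  })
  expect_true(all(diff(meds) > 0))    # non-decreasing in noise sd

  noisy <- dplyr::mutate(base, x = x + rnorm(length(tt), sd = 1.4),
                         y = y + rnorm(length(tt), sd = 1.4))
  med_by_stride <- sapply(c(1, 4, 8), function(k)
    stats::median(stride_speeds(noisy, f, "full", stride = k)))
  expect_true(all(diff(med_by_stride) < 0))  # non-increasing in stride
})

test_that("the paired comparison matches the closed-form t statistic and stats::t.test", {
  # fixes chosen so that per-fish u_og - u_river = 1, 2, 3
  gauges <- tibble::tibble(t = c(0, 1000), Q = 0, stage = 0)
  reach <- river_reach(gauges, tibble::tibble(stage = c(-1, 0, 1),
                                              volume = c(1, 2, 3) * 1e4),
                       La = 234)   # Q = 0 -> u_river = 0
  fixes <- dplyr::bind_rows(
    tibble::tibble(tag_id = "A", t = c(0, 100), x = c(0, 100)),
    tibble::tibble(tag_id = "B", t = c(0, 100), x = c(0, 200)),
    tibble::tibble(tag_id = "C", t = c(0, 100), x = c(0, 300)))
  g <- ground_vs_river(fixes, reach)
  expect_equal(g$mean_difference, 2)
  expect_equal(g$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(g$df, 2)
  ref <- stats::t.test(c(1, 2, 3))
  expect_equal(g$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(g$t, unname(ref$statistic), tolerance = 1e-12)
  td <- tidy(g)
  expect_equal(td$estimate, 2)

  # fish moving exactly at the river velocity -> zero difference, degenerate
  gauges2 <- tibble::tibble(t = c(0, 1000), Q = 100, stage = 0)
  reach2 <- river_reach(gauges2, tibble::tibble(stage = c(-1, 0, 1),
                                                volume = c(1, 2, 3) * 46800),
                        La = 234)  # u_river = 0.25
  fixes2 <- purrr::map_dfr(c("A", "B", "C"), function(tg)
    tibble::tibble(tag_id = tg, t = c(0, 100), x = c(0, 25)))
  g2 <- ground_vs_river(fixes2, reach2)
  expect_equal(g2$mean_difference, 0, tolerance = 1e-12)
  expect_true(g2$degenerate)
  expect_equal(g2$p_value, 1)
})

test_that("a prescribed rheotaxis offset is recovered from the paired comparison", {
  cfg <- scenario_config(behaviors = data.frame(
    label = "positive_rheotaxis", fraction = 1, swim_speed = 0.05,
    diel = FALSE))
  f <- gen_field(cfg, duration = 4000, lateral_profile = "uniform",
                 vertical_profile = "uniform")
  tr <- simulate_fish(f, cfg, n_fish = 6, release_span = 100, t_max = 4000,
                      seed = 3)
  fx <- tr |> dplyr::select(tag_id, t, x, y)
  g <- gen_gauges(f, cfg, times = c(0, 4000))
  vol <- cfg$channel$length * cfg$channel$width * cfg$channel$depth
  reach <- river_reach(g, tibble::tibble(
    stage = c(-1, 0, 1), volume = vol * (c(3, 4, 5) / 4)),
    La = cfg$channel$length)
  # uniform field: u_river = Q*L/V = u exactly; fish swim 0.05 upstream
  gv <- ground_vs_river(fx, reach)
  expect_equal(gv$mean_difference, -0.05, tolerance = 0.01)
})

test_that("behavior labels recover the prescribed policies", {
  rec_pos <- mk_records("A", 10, u_long = rnorm(10, -0.1, 0.01))
  rec_pas <- mk_records("B", 10, u_long = 0, v_lat = 0)
  rec_lat <- mk_records("C", 10, u_long = 0.001,
                        v_lat = rnorm(10, 0.1, 0.01))
  lab <- classify_behavior(dplyr::bind_rows(rec_pos, rec_pas, rec_lat))
  expect_equal(lab$label[lab$tag_id == "A"], "positive_rheotaxis")
  expect_equal(lab$label[lab$tag_id == "B"], "passive")
  expect_equal(lab$label[lab$tag_id == "C"], "lateral")
  short <- classify_behavior(mk_records("D", 3, u_long = -1))
  expect_true(is.na(short$label))
})

test_that("body-length normalization matches the printed conversions", {
  expect_equal(round(bl_normalize(0.15, 76.6), 1), 2.0)
  expect_equal(bl_normalize(0, 80), 0)
  expect_equal(bl_normalize(0.51, 85), 6.0)
  expect_error(bl_normalize(0.1, 0), "positive")
})

test_that("the exported GAM table has one weighted row per segment and range", {
  rec <- mk_records(c("A", "B"), 4, vranges = vrange_levels()) |>
    dplyr::mutate(hydro_speed = 0.4, vorticity = 0, depth = 4,
                  time_of_day = 12, u_river = 0.45, turbidity = 10) |>
    segment_weights()
  tab <- export_gam_table(rec)
  expect_equal(nrow(tab), 2 * 3 * 4)
  w <- tab |> dplyr::group_by(tag_id) |> dplyr::summarise(w = sum(weight))
  expect_equal(w$w, c(1, 1))
  expect_equal(tab$v_lat_abs, abs(rec$v_lat))
  expect_error(export_gam_table(mk_records("A", 2)), "missing")
})

test_that("summarize_swimming reports medians, CIs and occurrence per range", {
  set.seed(30)
  rec <- dplyr::bind_rows(lapply(sprintf("F%02d", 1:12), function(tg)
    mk_records(tg, 20, vranges = vrange_levels(),
               u_long = rnorm(60, -0.1, 0.04)))) |>
    segment_weights()
  s <- summarize_swimming(rec, n_boot = 200, seed = 5)
  td <- tidy(s)
  expect_equal(nrow(td), 3)
  expect_true(all(td$ci_lo <= td$median_u_long + 1e-9))
  expect_true(all(td$median_u_long <= td$ci_hi + 1e-9))
  expect_true(all(td$rheotaxis_weighted > 0.9))
  kde <- attr(s, "kde")
  expect_true(all(kde$density >= 0))
})
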