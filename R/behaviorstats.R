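#' Analysis weights for swim records
#'
#' Swimming biases how long a fish stays observable (an upstream swimmer
#' accrues more segments than a downstream one), so records are weighted
#' by the inverse of the individual's segment count, equalizing the total
#' weight per fish. When several vertical averaging ranges are pooled as
#' replicate measurements, an additional factor of `1/n_vranges`
#' (conventionally 1/3) avoids inflating the degrees of freedom.
#'
#' @param records Swim-record tibble with `tag_id` and `vrange`.
#' @param pool_vranges Apply the replicate factor? Default: yes when more
#'   than one vrange is present.
#' @return The records with a `weight` column.
#' @export
segment_weights <- function(records, pool_vranges = NULL) {
  nvr <- dplyr::n_distinct(records$vrange)
  if (is.null(pool_vranges)) pool_vranges <- nvr > 1
  fac <- if (pool_vranges) 1 / nvr else 1
  records |>
    dplyr::group_by(.data$tag_id, .data$vrange) |>
    dplyr::mutate(weight = fac / dplyr::n()) |>
    dplyr::ungroup()
}

#' Weighted median
#'
#' The smallest value whose cumulative normalized weight reaches 0.5.
#'
#' @param values Numeric vector.
#' @param weights Positive weights (recycled if scalar).
#' @return The weighted median.
#' @export
weighted_median <- function(values, weights = 1) {
  weights <- rep_len(weights, length(values))
  ok <- !is.na(values) & !is.na(weights)
  values <- values[ok]; weights <- weights[ok]
  if (length(values) == 0) return(NA_real_)
  ord <- order(values)
  cw <- cumsum(weights[ord]) / sum(weights)
  values[ord][which(cw >= 0.5)[1]]
}

#' Bootstrap confidence interval for the weighted median
#'
#' Draws `n_boot` resamples with replacement, with selection probability
#' proportional to weight (the same weighted sample that feeds the kernel
#' density estimates), takes the median of each, and reports the 5th and
#' 95th percentiles of the bootstrap medians.
#'
#' @inheritParams weighted_median
#' @param n_boot Number of bootstrap resamples; default 1000.
#' @param seed Integer seed.
#' @return A list: `median` (weighted), `ci` (length-2, 5--95%).
#' @export
weighted_median_ci <- function(values, weights = 1, n_boot = 1000, seed = 1) {
  stopifnot(n_boot >= 100)
  weights <- rep_len(weights, length(values))
  if (sum(weights) <= 0) stop("weights must sum to a positive value")
  med <- weighted_median(values, weights)
  set.seed(seed)
  n <- length(values)
  boots <- vapply(seq_len(n_boot), function(i) {
    stats::median(values[sample.int(n, n, replace = TRUE,
                                    prob = weights / sum(weights))])
  }, numeric(1))
  list(median = med,
       ci = unname(stats::quantile(boots, c(0.05, 0.95))))
}

#' Weighted Gaussian kernel density estimate
#'
#' Direct evaluation of a weighted Gaussian-kernel density on a regular
#' grid spanning the data plus three bandwidths. The default bandwidth is
#' Silverman's rule applied to the weighted standard deviation with the
#' effective sample size `(sum w)^2 / sum w^2`.
#'
#' @inheritParams weighted_median
#' @param bandwidth Kernel bandwidth; `NULL` for the weighted Silverman
#'   rule.
#' @param n_grid Grid size; default 512.
#' @return A tibble `x`, `density`; the density integrates to 1.
#' @export
weighted_kde <- function(values, weights = 1, bandwidth = NULL,
                         n_grid = 512) {
  weights <- rep_len(weights, length(values))
  ok <- !is.na(values) & !is.na(weights)
  values <- values[ok]; weights <- weights[ok] / sum(weights[ok])
  if (length(unique(values)) < 2 && is.null(bandwidth)) {
    stop("need at least 2 distinct values (or an explicit bandwidth)")
  }
  if (is.null(bandwidth)) {
    m <- sum(weights * values)
    s <- sqrt(sum(weights * (values - m)^2))
    n_eff <- 1 / sum(weights^2)
    bandwidth <- 0.9 * s * n_eff^(-1 / 5)
    if (bandwidth <= 0) stop("degenerate bandwidth")
  }
  grid <- seq(min(values) - 3 * bandwidth, max(values) + 3 * bandwidth,
              length.out = n_grid)
  dens <- vapply(grid, function(g) {
    sum(weights * stats::dnorm(g, mean = values, sd = bandwidth))
  }, numeric(1))
  tibble::tibble(x = grid, density = dens)
}

#' Occurrence of positive rheotaxis
#'
#' The weighted fraction of records swimming against the flow
#' (`u_long < 0`). The unweighted fraction is attached as the
#' `"unweighted"` attribute.
#'
#' @param records Swim-record tibble with `u_long` and `weight` columns
#'   (weight defaults to 1 if absent).
#' @return Weighted fraction in `[0, 1]`.
#' @export
rheotaxis_fraction <- function(records) {
  w <- if ("weight" %in% names(records)) records$weight else
    rep(1, nrow(records))
  ok <- !is.na(records$u_long)
  pos <- records$u_long[ok] < 0
  out <- sum(w[ok] * pos) / sum(w[ok])
  attr(out, "unweighted") <- mean(pos)
  out
}

#' Swim speeds at multiple strides
#'
#' Recomputes swim speeds from fix pairs `(i, i + stride)` instead of
#' consecutive fixes. Because uncorrelated positional noise biases speeds
#' upward by an amount that shrinks as the interval grows, comparing
#' strides bounds the contribution of telemetry noise (and path
#' sinuosity) to the speed distribution.
#'
#' @param fixes Ordered fix tibble.
#' @param field A [flow_field()].
#' @param vrange Vertical averaging range for the hydrodynamic reference.
#' @param stride Positive integer fix stride.
#' @param max_gap Maximum allowed pair separation (s); default
#'   `stride * 20`.
#' @return Numeric vector of swim speeds (m/s).
#' @export
stride_speeds <- function(fixes, field, vrange = "full", stride = 1,
                          max_gap = NULL) {
  stopifnot(stride >= 1)
  if (is.null(max_gap)) max_gap <- stride * 20
  segs <- fixes |>
    dplyr::arrange(.data$tag_id, .data$t) |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::mutate(
      t1 = dplyr::lead(.data$t, stride), x1 = dplyr::lead(.data$x, stride),
      y1 = dplyr::lead(.data$y, stride)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$t1), .data$t1 - .data$t <= max_gap,
                  .data$t1 > .data$t)
  if (nrow(segs) == 0) return(numeric(0))
  uog_u <- (segs$x1 - segs$x) / (segs$t1 - segs$t)
  uog_v <- (segs$y1 - segs$y) / (segs$t1 - segs$t)
  uv <- extract_velocity(field, (segs$x + segs$x1) / 2,
                         (segs$y + segs$y1) / 2, (segs$t + segs$t1) / 2,
                         vrange = vrange, strict = FALSE)
  sp <- sqrt((uog_u - uv$u)^2 + (uog_v - uv$v)^2)
  sp[!is.na(sp)]
}

#' Downstream movement versus mean river velocity
#'
#' Compares each fish's downstream velocity over ground, averaged over
#' its transit of the analysis region (net x-displacement over elapsed
#' time), with the mean river velocity over the same interval, by a
#' two-sided paired t-test. A positive mean difference of river minus
#' ground velocity means behavior slowed downstream movement.
#'
#' @param fixes QC'd fix tibble (`tag_id`, `t`, `x`).
#' @param reach A [river_reach()].
#' @param conf_level Confidence level for the mean-difference interval;
#'   default 0.90.
#' @return An object of class `gvr_test` with per-fish `pairs`, the mean
#'   difference (`u_og - u_river`), `t`, `df`, `p_value` and the
#'   confidence interval.
#' @export
ground_vs_river <- function(fixes, reach, conf_level = 0.90) {
  pairs <- fixes |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::summarise(
      t0 = min(.data$t), t1 = max(.data$t),
      u_og = (.data$x[which.max(.data$t)] - .data$x[which.min(.data$t)]) /
        (max(.data$t) - min(.data$t))) |>
    dplyr::filter(.data$t1 > .data$t0)
  pairs$u_river <- vapply(seq_len(nrow(pairs)), function(i) {
    tt <- seq(pairs$t0[i], pairs$t1[i], length.out = 25)
    mean(mean_river_velocity(reach, tt))
  }, numeric(1))
  if (nrow(pairs) < 2) stop("paired comparison needs at least 2 fish")
  d <- pairs$u_og - pairs$u_river
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    tstat <- NA_real_
    p <- if (md == 0) 1 else 0
    ci <- c(md, md)
    degenerate <- TRUE
  } else {
    se <- sdd / sqrt(n)
    tstat <- md / se
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
    q <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
    ci <- md + c(-1, 1) * q * se
    degenerate <- FALSE
  }
  structure(
    list(pairs = pairs, mean_difference = md, t = tstat, df = n - 1,
         p_value = p, conf_int = ci, conf_level = conf_level,
         degenerate = degenerate),
    class = "gvr_test"
  )
}

#' @export
print.gvr_test <- function(x, ...) {
  cat("<gvr_test> N =", x$df + 1, "fish; mean(u_og - u_river) =",
      format(x$mean_difference, digits = 3), "m/s\n")
  cat("  t =", format(x$t, digits = 4), " df =", x$df,
      " p =", format(x$p_value, digits = 3), "\n")
  cat("  ", round(100 * x$conf_level), "% CI [",
      format(x$conf_int[1], digits = 3), ",",
      format(x$conf_int[2], digits = 3), "]\n")
  invisible(x)
}

#' @rdname ground_vs_river
#' @param x A `gvr_test`.
#' @param ... Unused.
#' @method tidy gvr_test
#' @export
tidy.gvr_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_difference, statistic = x$t, df = x$df,
    p.value = x$p_value, conf.low = x$conf_int[1],
    conf.high = x$conf_int[2])
}

#' @rdname ground_vs_river
#' @method glance gvr_test
#' @export
glance.gvr_test <- function(x, ...) {
  tibble::tibble(n_fish = x$df + 1, mean_difference = x$mean_difference,
                 p.value = x$p_value, degenerate = x$degenerate)
}

#' Label a track's dominant behavior
#'
#' A declared heuristic on track-median flow-frame components: median
#' `u_long < -tau` is positive rheotaxis, `> tau` negative rheotaxis;
#' otherwise a median lateral speed above `tau_lat` is lateral swimming,
#' else passive transport. Tracks with fewer than `min_records` records
#' are unlabeled (`NA`).
#'
#' @param records Swim records of one vertical range with `tag_id`,
#'   `u_long`, `v_lat`.
#' @param tau,tau_lat Longitudinal and lateral thresholds (m/s); default
#'   0.05.
#' @param min_records Minimum records per track; default 5.
#' @return A tibble `tag_id`, `label`.
#' @export
classify_behavior <- function(records, tau = 0.05, tau_lat = 0.05,
                              min_records = 5) {
  records |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      med_u = stats::median(.data$u_long, na.rm = TRUE),
      med_lat = stats::median(abs(.data$v_lat), na.rm = TRUE)) |>
    dplyr::mutate(label = dplyr::case_when(
      .data$n < min_records ~ NA_character_,
      .data$med_u < -tau ~ "positive_rheotaxis",
      .data$med_u > tau ~ "negative_rheotaxis",
      .data$med_lat > tau_lat ~ "lateral",
      TRUE ~ "passive")) |>
    dplyr::select("tag_id", "label")
}

#' Body-length normalization of speed
#'
#' @param speed Speed (m/s).
#' @param fork_length_mm Fork length (mm), > 0.
#' @return Speed in body lengths per second.
#' @export
bl_normalize <- function(speed, fork_length_mm) {
  if (any(fork_length_mm <= 0)) stop("fork length must be positive")
  speed / (fork_length_mm / 1000)
}

#' Export the GAM covariate table
#'
#' One row per (segment, vertical range) with the response components,
#' all environmental covariates, the tag id and the analysis weight
#' (including the 1/3 replicate factor when vranges are pooled). Model
#' fitting itself is out of scope; the table is the hand-off.
#'
#' @param records Swim records with covariates and weights attached.
#' @return A tibble ready for smooth-model fitting.
#' @export
export_gam_table <- function(records) {
  need <- c("tag_id", "vrange", "u_long", "v_lat", "hydro_speed",
            "vorticity", "depth", "time_of_day", "u_river", "turbidity",
            "weight")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("records are missing: ", paste(miss, collapse = ", "),
         " (run swim_records |> attach_covariates |> segment_weights)")
  }
  records |>
    dplyr::transmute(
      tag_id = .data$tag_id, vrange = .data$vrange,
      u_long = .data$u_long, v_lat_abs = abs(.data$v_lat),
      hydro_speed = .data$hydro_speed, vorticity = .data$vorticity,
      depth = .data$depth, time_of_day = .data$time_of_day,
      u_river = .data$u_river, turbidity = .data$turbidity,
      weight = .data$weight)
}

#' Weighted distributional summary of swimming
#'
#' For each vertical averaging range: the weighted median longitudinal
#' swimming velocity with its bootstrapped 5--95% CI, the weighted
#' occurrence of positive rheotaxis, and a weighted kernel density
#' estimate of `u_long`.
#'
#' @param records Weighted swim records (`u_long`, `vrange`, `weight`).
#' @param n_boot Bootstrap resamples; default 1000.
#' @param seed Integer seed.
#' @return A `swim_summary`: tibble of per-vrange statistics with the KDE
#'   curves in the `kde` attribute.
#' @export
summarize_swimming <- function(records, n_boot = 1000, seed = 1) {
  stopifnot(all(c("u_long", "vrange", "weight") %in% names(records)))
  stats_tbl <- purrr::imap_dfr(split(records, records$vrange),
                               function(df, vr) {
    df <- df[df$frame_defined %in% c(TRUE, NA) & !is.na(df$u_long), ]
    ci <- weighted_median_ci(df$u_long, df$weight, n_boot = n_boot,
                             seed = seed)
    rf <- rheotaxis_fraction(df)
    tibble::tibble(
      vrange = vr,
      median_u_long = ci$median, ci_lo = ci$ci[1], ci_hi = ci$ci[2],
      rheotaxis_weighted = as.numeric(rf),
      rheotaxis_unweighted = attr(rf, "unweighted"),
      n_individuals = dplyr::n_distinct(df$tag_id),
      n_records = nrow(df))
  })
  kde <- purrr::imap_dfr(split(records, records$vrange), function(df, vr) {
    df <- df[!is.na(df$u_long), ]
    k <- weighted_kde(df$u_long, df$weight)
    k$vrange <- vr
    k
  })
  structure(stats_tbl, class = c("swim_summary", class(stats_tbl)),
            kde = kde)
}

#' @rdname summarize_swimming
#' @param x A `swim_summary`.
#' @param ... Unused.
#' @method tidy swim_summary
#' @export
tidy.swim_summary <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}
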