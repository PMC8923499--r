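#' Generate a hydrophone array
#'
#' Places receivers on a staggered grid along the channel axis so that, with
#' zero jitter, adjacent receivers are exactly the nominal spacing apart.
#' Gaussian placement jitter (if any) is added independently to x and y. The
#' first receiver is designated the synchronization reference (its clock
#' defines the time base); the rest alternate between cabled and autonomous
#' roles.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed for the placement jitter.
#' @return A tibble of hydrophones: `id`, `x`, `y`, `z`, `role`.
#' @export
gen_array <- function(config, seed = 1) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_receivers
  if (n < 3) stop("multilateration needs at least 3 receivers")
  chan <- config$channel
  off <- min(chan$width / 6, config$nominal_spacing / 4)
  dx <- sqrt(config$nominal_spacing^2 - (2 * off)^2)
  x0 <- (chan$length - (n - 1) * dx) / 2
  x <- x0 + (seq_len(n) - 1) * dx
  y <- chan$width / 2 + off * ifelse(seq_len(n) %% 2 == 1, 1, -1)
  if (config$array_jitter_sd > 0) {
    set.seed(seed)
    x <- x + stats::rnorm(n, sd = config$array_jitter_sd)
    y <- y + stats::rnorm(n, sd = config$array_jitter_sd)
  }
  role <- rep(c("cabled", "autonomous"), length.out = n)
  role[1] <- "reference"
  tibble::tibble(
    id = sprintf("R%02d", seq_len(n)),
    x = x, y = y,
    z = -chan$depth + 0.5,
    role = role
  )
}

#' Generate true piecewise-linear clock drifts
#'
#' Draws, for every non-reference receiver, a continuous piecewise-linear
#' clock-offset function on a regular knot grid: knot offsets follow a
#' random walk clipped to `drift_amplitude`. The reference receiver's
#' offset is identically zero.
#'
#' @param array Hydrophone tibble from [gen_array()].
#' @param config A [scenario_config()].
#' @param t0,t1 Time span to cover (s).
#' @param seed Integer seed.
#' @return A tibble `receiver_id`, `knot_time`, `offset` (s).
#' @export
gen_drifts <- function(array, config, t0, t1, seed = 1) {
  set.seed(seed)
  knots <- seq(t0, t1 + config$drift_knot_interval, by = config$drift_knot_interval)
  amp <- config$drift_amplitude
  ref <- array$id[array$role == "reference"][1]
  purrr::map_dfr(array$id, function(id) {
    if (id == ref) {
      off <- rep(0, length(knots))
    } else {
      step <- stats::rnorm(length(knots), sd = amp / 3)
      off <- pmin(pmax(cumsum(step), -amp), amp)
    }
    tibble::tibble(receiver_id = id, knot_time = knots, offset = off)
  })
}

# Evaluate a piecewise-linear offset table at arbitrary times (flat beyond
# the end knots). `drifts` as returned by gen_drifts().
.eval_offsets <- function(drifts, receiver_id, t) {
  out <- numeric(length(t))
  for (id in unique(receiver_id)) {
    sel <- receiver_id == id
    d <- drifts[drifts$receiver_id == id, ]
    if (nrow(d) == 0) next
    if (nrow(d) == 1) {
      out[sel] <- d$offset
    } else {
      out[sel] <- stats::approx(d$knot_time, d$offset, xout = t[sel],
                                rule = 2)$y
    }
  }
  out
}

#' Generate an analytic channel flow field
#'
#' Builds a separable sheared channel flow on a rectilinear grid:
#' `u(x, y, z, t) = U(t) * f_lat(y) * f_log(z)`, `v = 0`, where `f_log` is a
#' log-law vertical profile over the roughness length `z0` (normalized to 1
#' at the surface), `f_lat` a parabolic lateral profile vanishing at the
#' banks (normalized to 1 at the centerline), and `U(t)` the surface
#' centerline speed, optionally modulated by a sinusoidal tide. The bed is
#' flat at `-depth` and the surface at 0.
#'
#' @param config A [scenario_config()].
#' @param duration Temporal extent of the field (s); default one day.
#' @param nx,ny,nz,nt Grid resolution; `nt` defaults to 2 for steady flow
#'   and to ~10-minute steps when a tide is configured.
#' @param lateral_profile `"parabolic"` (default) or `"uniform"`.
#' @param vertical_profile `"loglaw"` (default) or `"uniform"`.
#' @return A [flow_field()].
#' @export
gen_field <- function(config, duration = 86400,
                      nx = 5, ny = 26, nz = 25, nt = NULL,
                      lateral_profile = c("parabolic", "uniform"),
                      vertical_profile = c("loglaw", "uniform")) {
  stopifnot(inherits(config, "scenario_config"))
  lateral_profile <- match.arg(lateral_profile)
  vertical_profile <- match.arg(vertical_profile)
  chan <- config$channel
  if (chan$roughness_z0 >= chan$depth) stop("roughness z0 must be < depth")
  if (is.null(nt)) {
    nt <- if (chan$tidal_amplitude > 0) max(2, ceiling(duration / 600)) else 2
  }
  x <- seq(0, chan$length, length.out = nx)
  y <- seq(0, chan$width, length.out = ny)
  z <- seq(-chan$depth + max(1.5 * chan$roughness_z0, 0.02), 0, length.out = nz)
  t <- seq(0, duration, length.out = nt)
  U <- chan$peak_speed +
    chan$tidal_amplitude * sin(2 * pi * t / chan$tidal_period)
  f_lat <- switch(lateral_profile,
                  uniform = rep(1, ny),
                  parabolic = 4 * (y / chan$width) * (1 - y / chan$width))
  f_log <- switch(vertical_profile,
                  uniform = rep(1, nz),
                  loglaw = {
                    p <- log((z + chan$depth) / chan$roughness_z0) /
                      log(chan$depth / chan$roughness_z0)
                    pmax(p, 0)
                  })
  u <- array(0, c(nx, ny, nz, nt))
  base <- outer(rep(1, nx), outer(f_lat, f_log))
  for (k in seq_len(nt)) u[, , , k] <- U[k] * base
  flow_field(x = x, y = y, z = z, t = t, u = u, v = 0,
             bed = -chan$depth, surface = 0)
}

.flow_dir <- function(uv, eps = 1e-3) {
  sp <- sqrt(uv$u^2 + uv$v^2)
  fx <- ifelse(sp >= eps, uv$u / sp, NA_real_)
  fy <- ifelse(sp >= eps, uv$v / sp, NA_real_)
  list(fx = fx, fy = fy, speed = sp)
}

# Swim-velocity policy for one step; river right is the clockwise
# perpendicular (f_y, -f_x) of the downstream unit vector.
.behavior_swim <- function(label, speed, fx, fy, tod_h, diel) {
  s <- speed
  if (isTRUE(diel)) s <- s * (0.5 + 0.5 * cos(2 * pi * (tod_h - 14) / 24))
  ok <- !is.na(fx)
  sw_u <- numeric(length(fx))
  sw_v <- numeric(length(fx))
  if (label == "positive_rheotaxis") {
    sw_u <- ifelse(ok, -s * fx, 0); sw_v <- ifelse(ok, -s * fy, 0)
  } else if (label == "negative_rheotaxis") {
    sw_u <- ifelse(ok, s * fx, 0); sw_v <- ifelse(ok, s * fy, 0)
  } else if (label == "lateral") {
    sw_u <- ifelse(ok, s * fy, 0); sw_v <- ifelse(ok, -s * fx, 0)
  }
  list(u = sw_u, v = sw_v)
}

#' Simulate fish moving through the flow field
#'
#' Integrates fish positions with a fixed-step Euler update
#' `dx = (u_h(x, t) + u_swim(t)) * dt`, where `u_h` is the vertically
#' averaged water velocity at the fish's location and `u_swim` follows the
#' fish's prescribed behavior: swimming against the local depth-averaged
#' flow (positive rheotaxis), with it (negative rheotaxis), toward river
#' right (lateral), or not at all (passive transport). Tracks terminate
#' when a fish leaves the wetted domain.
#'
#' @param field A [flow_field()].
#' @param config A [scenario_config()]; behavior mix, swim speeds and fork
#'   lengths are drawn from it.
#' @param n_fish Number of fish; default 30.
#' @param release_span Releases are staggered uniformly over `[0,
#'   release_span]` seconds; default 600.
#' @param dt Euler step (s); default 0.5 (much smaller than the ping
#'   interval, so integration error is below telemetry noise scale).
#' @param t_max Hard stop for the integration (s).
#' @param advect_vrange Vertical range whose averaged velocity advects the
#'   fish; default `"full"`.
#' @param max_track_s Per-fish cap on track duration (s); default 5400.
#' @param seed Integer seed.
#' @return A tibble of true track states: `tag_id`, `t`, `x`, `y`,
#'   `swim_u`, `swim_v`, `behavior`, with a `fish` attribute table
#'   (`tag_id`, `behavior`, `fork_length_mm`, `t_release`).
#' @export
simulate_fish <- function(field, config, n_fish = 30, release_span = 600,
                          dt = 0.5, t_max = NULL, advect_vrange = "full",
                          max_track_s = 5400, seed = 1) {
  stopifnot(inherits(field, "flow_field"), inherits(config, "scenario_config"))
  set.seed(seed)
  beh <- config$behaviors
  counts <- floor(beh$fraction * n_fish)
  while (sum(counts) < n_fish) {
    k <- which.max(beh$fraction * n_fish - counts)
    counts[k] <- counts[k] + 1
  }
  labels <- rep(beh$label, counts)[seq_len(n_fish)]
  speeds <- rep(beh$swim_speed, counts)[seq_len(n_fish)]
  diel <- rep(beh$diel, counts)[seq_len(n_fish)]
  fl <- stats::rnorm(n_fish, config$fork_length_mm[1], config$fork_length_mm[2])
  if (is.null(t_max)) t_max <- max(field$t)
  xr <- range(field$x); yr <- range(field$y)
  t0 <- stats::runif(n_fish, 0, release_span)
  tag <- sprintf("F%03d", seq_len(n_fish))
  n_steps <- ceiling(min(max_track_s, t_max) / dt)
  X <- matrix(NA_real_, n_fish, n_steps + 1)
  Y <- matrix(NA_real_, n_fish, n_steps + 1)
  SU <- matrix(NA_real_, n_fish, n_steps + 1)
  SV <- matrix(NA_real_, n_fish, n_steps + 1)
  Tm <- matrix(NA_real_, n_fish, n_steps + 1)
  X[, 1] <- xr[1] + 0.02 * diff(xr)
  Y[, 1] <- yr[1] + diff(yr) * stats::runif(n_fish, 0.3, 0.7)
  Tm[, 1] <- t0
  alive <- rep(TRUE, n_fish)
  margin <- 0.002 * diff(xr)
  # persistent heading: in slack water fish keep their last flow-derived
  # orientation instead of ceasing to swim
  hx <- rep(1, n_fish); hy <- rep(0, n_fish)
  for (s in seq_len(n_steps)) {
    idx <- which(alive)
    if (length(idx) == 0) break
    tq <- pmin(Tm[idx, s], max(field$t))
    uv <- extract_velocity(field, X[idx, s], Y[idx, s], tq,
                           vrange = advect_vrange, strict = FALSE)
    fd <- .flow_dir(uv)
    def <- !is.na(fd$fx)
    hx[idx[def]] <- fd$fx[def]
    hy[idx[def]] <- fd$fy[def]
    fd$fx <- hx[idx]; fd$fy <- hy[idx]
    sw_u <- numeric(length(idx)); sw_v <- numeric(length(idx))
    for (lab in unique(labels[idx])) {
      m <- labels[idx] == lab
      sw <- .behavior_swim(lab, speeds[idx][m], fd$fx[m], fd$fy[m],
                           (Tm[idx, s][m] / 3600) %% 24, diel[idx][m][1])
      sw_u[m] <- sw$u; sw_v[m] <- sw$v
    }
    dead <- is.na(uv$u)
    SU[idx, s] <- ifelse(dead, NA_real_, sw_u)
    SV[idx, s] <- ifelse(dead, NA_real_, sw_v)
    newx <- X[idx, s] + (uv$u + sw_u) * dt
    newy <- Y[idx, s] + (uv$v + sw_v) * dt
    newt <- Tm[idx, s] + dt
    inb <- !dead & newx > xr[1] + margin & newx < xr[2] - margin &
      newy >= yr[1] & newy <= yr[2] & newt <= t_max
    ok <- idx[inb]
    X[ok, s + 1] <- newx[inb]
    Y[ok, s + 1] <- newy[inb]
    Tm[ok, s + 1] <- newt[inb]
    alive[idx[!inb]] <- FALSE
  }
  out <- purrr::map_dfr(seq_len(n_fish), function(k) {
    valid <- which(!is.na(Tm[k, ]))
    su <- SU[k, valid]; sv <- SV[k, valid]
    nlast <- length(valid)
    if (nlast > 1 && is.na(su[nlast])) {
      su[nlast] <- su[nlast - 1]; sv[nlast] <- sv[nlast - 1]
    }
    su[is.na(su)] <- 0; sv[is.na(sv)] <- 0
    tibble::tibble(tag_id = tag[k], t = Tm[k, valid], x = X[k, valid],
                   y = Y[k, valid], swim_u = su, swim_v = sv,
                   behavior = labels[k])
  })
  attr(out, "fish") <- tibble::tibble(
    tag_id = tag, behavior = labels, swim_speed = speeds,
    fork_length_mm = fl, t_release = t0
  )
  out
}

#' Simulate acoustic detections of tags and beacons
#'
#' Tags emit at the pulse-rate interval plus Gaussian jitter while inside
#' the array; each hydrophone doubles as a synchronization beacon emitting
#' on a fixed schedule. Every emission is detected by each receiver with
#' probability `detection_prob`; the raw receiver timestamp is
#' `emission + distance / c + clock_offset(receiver, t) + noise`. A
#' `corrupt_frac` of detections receive a multipath-like positive extra
#' delay, either as an appended delayed duplicate (default) or in place.
#' The returned truth record carries emission times, the injected offsets
#' and the corrupted detection ids, so downstream stages can be scored
#' against ground truth.
#'
#' @param tracks True tracks from [simulate_fish()] (may be `NULL` or empty
#'   for a beacons-only set).
#' @param array Hydrophone tibble from [gen_array()].
#' @param config A [scenario_config()].
#' @param t_span Length-2 numeric: time window for beacon emissions (s).
#' @param drifts True clock offsets from [gen_drifts()], or `NULL` for
#'   drift-free clocks.
#' @param beacons Include beacon-to-beacon pings? Default `TRUE`.
#' @param seed Integer seed.
#' @return A list with `detections` (tibble: `det_id`, `receiver_id`,
#'   `source_id`, `source_kind`, `raw_time`) and `truth` (list of
#'   `emissions`, `drifts`, `corrupted_ids`, `arrivals`).
#' @export
simulate_detections <- function(tracks, array, config,
                                t_span = NULL, drifts = NULL,
                                beacons = TRUE, seed = 1) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  c_sound <- config$sound_speed
  emis <- list()
  if (!is.null(tracks) && nrow(tracks) > 0) {
    emis$tags <- purrr::map_dfr(split(tracks, tracks$tag_id), function(tr) {
      span <- max(tr$t) - min(tr$t)
      n_ping <- floor(span / config$pri) + 1L
      if (n_ping < 1) return(NULL)
      gaps <- config$pri + stats::rnorm(n_ping - 1, sd = config$pri_jitter_sd)
      te <- min(tr$t) + c(0, cumsum(pmax(gaps, 0.1)))
      te <- te[te <= max(tr$t)]
      tibble::tibble(
        source_id = tr$tag_id[1], source_kind = "tag", t_emit = te,
        x = stats::approx(tr$t, tr$x, xout = te)$y,
        y = stats::approx(tr$t, tr$y, xout = te)$y,
        z = -config$tag_depth
      )
    })
  }
  if (beacons) {
    if (is.null(t_span)) {
      t_span <- if (length(emis)) c(0, max(emis$tags$t_emit)) else c(0, 3600)
    }
    nb <- nrow(array)
    emis$beacons <- purrr::map_dfr(seq_len(nb), function(i) {
      phase <- (i - 1) * config$beacon_interval / nb
      te <- seq(t_span[1] + phase, t_span[2], by = config$beacon_interval)
      tibble::tibble(source_id = array$id[i], source_kind = "beacon",
                     t_emit = te, x = array$x[i], y = array$y[i],
                     z = array$z[i])
    })
  }
  emissions <- dplyr::bind_rows(emis)
  if (nrow(emissions) == 0) {
    return(list(
      detections = tibble::tibble(det_id = integer(), receiver_id = character(),
                                  source_id = character(),
                                  source_kind = character(),
                                  raw_time = numeric()),
      truth = list(emissions = emissions, drifts = drifts,
                   corrupted_ids = integer(),
                   arrivals = tibble::tibble())
    ))
  }
  emissions$ping_id <- seq_len(nrow(emissions))
  ne <- nrow(emissions); nr <- nrow(array)
  ei <- rep(seq_len(ne), times = nr)
  ri <- rep(seq_len(nr), each = ne)
  d <- sqrt((emissions$x[ei] - array$x[ri])^2 +
              (emissions$y[ei] - array$y[ri])^2 +
              (emissions$z[ei] - array$z[ri])^2)
  keep <- stats::runif(length(ei)) < config$detection_prob
  ei <- ei[keep]; ri <- ri[keep]; d <- d[keep]
  t_arr <- emissions$t_emit[ei] + d / c_sound
  offset <- if (is.null(drifts)) 0 else .eval_offsets(drifts, array$id[ri], t_arr)
  noise <- if (config$arrival_noise_sd > 0) {
    stats::rnorm(length(ei), sd = config$arrival_noise_sd)
  } else 0
  det <- tibble::tibble(
    receiver_id = array$id[ri],
    source_id = emissions$source_id[ei],
    source_kind = emissions$source_kind[ei],
    raw_time = t_arr + offset + noise,
    ping_id = emissions$ping_id[ei],
    t_arrival = t_arr
  )
  corrupt_row0 <- integer()
  n_corrupt <- stats::rbinom(1, nrow(det), config$corrupt_frac)
  if (n_corrupt > 0) {
    pick <- sample.int(nrow(det), n_corrupt)
    delay <- stats::runif(n_corrupt, config$corrupt_delay_range[1],
                          config$corrupt_delay_range[2])
    if (config$corrupt_mode == "duplicate") {
      dup <- det[pick, ]
      dup$raw_time <- dup$raw_time + delay
      det <- dplyr::bind_rows(det, dup)
      corrupt_row0 <- nrow(det) - n_corrupt + seq_len(n_corrupt)
    } else {
      det$raw_time[pick] <- det$raw_time[pick] + delay
      corrupt_row0 <- pick
    }
  }
  det$row0 <- seq_len(nrow(det))
  det <- det[order(det$receiver_id, det$raw_time), ]
  det$det_id <- seq_len(nrow(det))
  corrupted_ids <- det$det_id[det$row0 %in% corrupt_row0]
  detections <- det[, c("det_id", "receiver_id", "source_id", "source_kind",
                        "raw_time")]
  list(
    detections = detections,
    truth = list(
      emissions = emissions,
      drifts = drifts,
      corrupted_ids = sort(corrupted_ids),
      arrivals = det[, c("det_id", "receiver_id", "source_id", "ping_id",
                         "t_arrival")]
    )
  )
}

#' Generate gauge time series from the flow field
#'
#' Discharge is the cross-sectionally integrated flux of the field at the
#' upstream section (trapezoidal integration of the depth-integrated
#' velocity across the channel); stage is the spatial mean free surface; a
#' smooth synthetic turbidity series is included for covariate plumbing.
#'
#' @param field A [flow_field()].
#' @param config A [scenario_config()].
#' @param times Times at which to evaluate (s); defaults to the field's
#'   time grid (or 10-minute steps across it when the grid is coarse).
#' @return A tibble `t`, `Q` (m^3/s), `stage` (m), `turbidity` (NTU).
#' @export
gen_gauges <- function(field, config, times = NULL) {
  stopifnot(inherits(field, "flow_field"))
  if (is.null(times)) {
    times <- if (length(field$t) > 2) field$t else
      seq(min(field$t), max(field$t), length.out = 25)
  }
  y <- field$y
  x0 <- min(field$x)
  Q <- vapply(times, function(tt) {
    uv <- extract_velocity(field, rep(x0, length(y)), y, tt,
                           vrange = "full", strict = FALSE)
    depth <- local_depth(field, rep(x0, length(y)), y, tt, strict = FALSE)
    flux <- ifelse(is.na(uv$u), 0, uv$u * depth)
    sum(diff(y) * (utils::head(flux, -1) + flux[-1]) / 2)
  }, numeric(1))
  stage <- vapply(times, function(tt) {
    mean(.interp_xyt(field$surface, field,
                     rep(mean(field$x), length(y)), y, rep(tt, length(y))))
  }, numeric(1))
  tibble::tibble(
    t = times, Q = Q, stage = stage,
    turbidity = 10 + 2 * sin(2 * pi * times / 86400)
  )
}
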