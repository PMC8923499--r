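#' Build segments from consecutive fixes
#'
#' A segment joins two successive relocations of one tag; its velocity
#' over ground is the vector displacement divided by the elapsed time, and
#' its midpoint (where hydrodynamic quantities are later sampled) is the
#' spatial and temporal midpoint of the pair. Pairs separated by more than
#' `max_gap` (missed pings) do not form segments.
#'
#' @param fixes Ordered fix tibble (`tag_id`, `t`, `x`, `y`).
#' @param max_gap Maximum segment duration (s); default 20 (4 pulse-rate
#'   intervals).
#' @return A tibble of segments: `tag_id`, `t0`, `t1`, `x0`, `y0`, `x1`,
#'   `y1`, `uog_u`, `uog_v`, `xm`, `ym`, `tm`.
#' @export
make_segments <- function(fixes, max_gap = 20) {
  fixes |>
    dplyr::arrange(.data$tag_id, .data$t) |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::mutate(
      t1 = dplyr::lead(.data$t), x1 = dplyr::lead(.data$x),
      y1 = dplyr::lead(.data$y)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$t1), .data$t1 - .data$t <= max_gap,
                  .data$t1 > .data$t) |>
    dplyr::transmute(
      tag_id = .data$tag_id,
      t0 = .data$t, t1 = .data$t1,
      x0 = .data$x, y0 = .data$y, x1 = .data$x1, y1 = .data$y1,
      uog_u = (.data$x1 - .data$x0) / (.data$t1 - .data$t0),
      uog_v = (.data$y1 - .data$y0) / (.data$t1 - .data$t0),
      xm = (.data$x0 + .data$x1) / 2,
      ym = (.data$y0 + .data$y1) / 2,
      tm = (.data$t0 + .data$t1) / 2)
}

#' Rotate swim vectors into the local flow frame
#'
#' Projects a swim-velocity vector onto the downstream unit vector `f`
#' (longitudinal component, positive downstream so negative values mean
#' positive rheotaxis) and onto the river-right perpendicular
#' `(f_y, -f_x)` (lateral component, positive toward river right --- the
#' right of an observer facing downstream).
#'
#' @param us_u,us_v Swim-velocity components (m/s), vectorized.
#' @param fx,fy Downstream unit-vector components (from depth-averaged
#'   flow).
#' @return A tibble `u_long`, `v_lat` (m/s).
#' @export
rotate_to_flow <- function(us_u, us_v, fx, fy) {
  tibble::tibble(
    u_long = us_u * fx + us_v * fy,
    v_lat = us_u * fy - us_v * fx
  )
}

#' Compute swim-velocity records for segments
#'
#' For every segment and requested vertical averaging range, extracts the
#' hydrodynamic velocity at the segment midpoint, forms the swim velocity
#' as the vector difference `u_s = u_og - u_h`, and rotates it into the
#' local flow frame. The frame orientation uses the depth-averaged
#' (full-depth) flow direction for all vertical ranges; records at
#' near-slack midpoints (depth-averaged speed below `eps`) keep their
#' vector components but have undefined flow-frame components and are
#' flagged. Segments whose midpoint falls dry or off-grid are skipped and
#' logged.
#'
#' @param segments Segment tibble from [make_segments()].
#' @param field A [flow_field()].
#' @param vranges Character vector of vertical ranges; default all three.
#' @param eps Minimum depth-averaged flow speed for a defined flow frame
#'   (m/s); default 1e-3.
#' @return A tibble with one row per (segment, vrange): segment fields
#'   plus `vrange`, `uh_u`, `uh_v`, `us_u`, `us_v`, `u_long`, `v_lat`,
#'   `frame_defined`. Skipped segments are reported in the `skipped`
#'   attribute.
#' @export
swim_records <- function(segments, field, vranges = vrange_levels(),
                         eps = 1e-3) {
  if (nrow(segments) == 0) {
    return(tibble::tibble())
  }
  full_uv <- extract_velocity(field, segments$xm, segments$ym, segments$tm,
                              vrange = "full", strict = FALSE)
  fd <- .flow_dir(full_uv, eps = eps)
  recs <- purrr::map_dfr(vranges, function(vr) {
    uv <- extract_velocity(field, segments$xm, segments$ym, segments$tm,
                           vrange = vr, strict = FALSE)
    us_u <- segments$uog_u - uv$u
    us_v <- segments$uog_v - uv$v
    rot <- rotate_to_flow(us_u, us_v, fd$fx, fd$fy)
    dplyr::bind_cols(
      segments,
      tibble::tibble(vrange = vr, uh_u = uv$u, uh_v = uv$v,
                     us_u = us_u, us_v = us_v,
                     u_long = rot$u_long, v_lat = rot$v_lat,
                     frame_defined = !is.na(fd$fx)))
  })
  dry <- is.na(recs$uh_u)
  attr(recs, "skipped") <- recs[dry, c("tag_id", "tm", "xm", "ym", "vrange")]
  recs[!dry, ]
}

#' Attach environmental covariates to swim records
#'
#' Fills, at each segment midpoint: the hydrodynamic speed and vorticity
#' for the record's own vertical range, the local water depth, the local
#' time of day, the mean river velocity, and turbidity joined by nearest
#' gauge time (within 30 minutes, else missing).
#'
#' @param records Swim-record tibble from [swim_records()].
#' @param field A [flow_field()].
#' @param reach Optional [river_reach()] supplying `u_river` and (through
#'   its gauges) turbidity.
#' @param utc_offset Hours added to UTC to get local time; default 0.
#' @param h Vorticity stencil half-width (m); default 2.
#' @return The records with columns `hydro_speed`, `vorticity`, `depth`,
#'   `time_of_day`, `u_river`, `turbidity`.
#' @export
attach_covariates <- function(records, field, reach = NULL, utc_offset = 0,
                              h = 2) {
  records$hydro_speed <- sqrt(records$uh_u^2 + records$uh_v^2)
  out <- purrr::map_dfr(split(records, records$vrange), function(df) {
    df$vorticity <- vorticity(field, df$xm, df$ym, df$tm,
                              vrange = df$vrange[1], h = h, strict = FALSE)
    df
  })
  out <- out[order(out$vrange, out$tag_id, out$t0), ]
  out$depth <- local_depth(field, out$xm, out$ym, out$tm, strict = FALSE)
  out$time_of_day <- ((out$tm / 3600 + utc_offset) %% 24)
  if (!is.null(reach)) {
    out$u_river <- tryCatch(mean_river_velocity(reach, out$tm),
                            error = function(e) rep(NA_real_, nrow(out)))
    g <- reach$gauges
    if ("turbidity" %in% names(g)) {
      nearest <- vapply(out$tm, function(tt) {
        k <- which.min(abs(g$t - tt))
        if (abs(g$t[k] - tt) <= 1800) g$turbidity[k] else NA_real_
      }, numeric(1))
      out$turbidity <- nearest
    } else {
      out$turbidity <- NA_real_
    }
  } else {
    out$u_river <- NA_real_
    out$turbidity <- NA_real_
  }
  out
}
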