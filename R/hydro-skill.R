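#' Hydrodynamic model skill metrics
#'
#' Compares modeled against observed horizontal velocity vectors. The bias
#' vector is the component-wise mean of the model-minus-observation
#' differences,
#' \deqn{b = \langle m_i - o_i \rangle,}
#' and the unbiased root-mean-square error is the RMS of the differences
#' after removing that bias,
#' \deqn{uRMSE = \sqrt{\langle \| m_i - o_i - b \|^2 \rangle},}
#' reported for the vector magnitude and for each component. Target-diagram
#' coordinates place longitudinal bias on the ordinate and uRMSE on the
#' abscissa, signed by whether the model under- or over-predicts the
#' variance of the observed speeds.
#'
#' @param pairs A data frame with columns `mu`, `mv` (modeled u, v) and
#'   `ou`, `ov` (observed u, v), one row per paired sample (m/s).
#' @return A one-row tibble: `bias_u`, `bias_v`, `urmse_total`, `urmse_u`,
#'   `urmse_v`, `target_x`, `target_y`, `n`.
#' @export
calibration_metrics <- function(pairs) {
  stopifnot(all(c("mu", "mv", "ou", "ov") %in% names(pairs)))
  if (nrow(pairs) < 2) stop("skill metrics need at least 2 paired samples")
  du <- pairs$mu - pairs$ou
  dv <- pairs$mv - pairs$ov
  bu <- mean(du)
  bv <- mean(dv)
  urmse_u <- sqrt(mean((du - bu)^2))
  urmse_v <- sqrt(mean((dv - bv)^2))
  urmse_total <- sqrt(mean((du - bu)^2 + (dv - bv)^2))
  sgn <- sign(stats::sd(sqrt(pairs$mu^2 + pairs$mv^2)) -
                stats::sd(sqrt(pairs$ou^2 + pairs$ov^2)))
  if (sgn == 0) sgn <- 1
  tibble::tibble(
    bias_u = bu, bias_v = bv,
    urmse_total = urmse_total, urmse_u = urmse_u, urmse_v = urmse_v,
    target_x = sgn * urmse_total, target_y = bu,
    n = nrow(pairs)
  )
}

#' River reach for mean-velocity estimation
#'
#' Bundles the reach-scale quantities needed to convert a discharge record
#' into a mean advective velocity: the characteristic flow-path length
#' `La`, a monotone stage-to-wetted-volume curve, and gauge series of
#' discharge and stage.
#'
#' @param gauges Data frame with columns `t` (s), `Q` (m^3/s), `stage` (m);
#'   may also carry `turbidity`.
#' @param volume_curve Data frame with columns `stage` (m) and `volume`
#'   (m^3), strictly increasing in both.
#' @param La Characteristic length of flow paths through the reach (m);
#'   default 234.
#' @return An object of class `river_reach`.
#' @export
river_reach <- function(gauges, volume_curve, La = 234) {
  stopifnot(all(c("t", "Q", "stage") %in% names(gauges)),
            all(c("stage", "volume") %in% names(volume_curve)),
            La > 0, all(volume_curve$volume > 0))
  if (is.unsorted(volume_curve$stage, strictly = TRUE)) {
    stop("volume_curve stage values must be strictly increasing")
  }
  structure(
    list(gauges = tibble::as_tibble(gauges),
         volume_curve = tibble::as_tibble(volume_curve),
         La = La),
    class = "river_reach"
  )
}

#' Mean river velocity
#'
#' The reach-averaged advective velocity `u_river(t) = Q(t) * La / V(t)`,
#' where `V(t)` is the wetted volume at the instantaneous stage. Gauge
#' series are interpolated linearly in time; stages outside the volume
#' curve's domain are rejected.
#'
#' @param reach A [river_reach()].
#' @param t Times (s) at which to evaluate, vectorized.
#' @return Numeric vector of mean river velocities (m/s).
#' @export
mean_river_velocity <- function(reach, t) {
  stopifnot(inherits(reach, "river_reach"))
  g <- reach$gauges
  if (any(t < min(g$t) | t > max(g$t))) {
    stop("requested time outside the gauge record")
  }
  Q <- stats::approx(g$t, g$Q, xout = t)$y
  stage <- stats::approx(g$t, g$stage, xout = t)$y
  vc <- reach$volume_curve
  if (any(stage < min(vc$stage) | stage > max(vc$stage))) {
    stop("stage outside the volume curve's domain")
  }
  V <- stats::approx(vc$stage, vc$volume, xout = stage)$y
  Q * reach$La / V
}
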