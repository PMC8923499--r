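#' Synthetic study scenario configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate
#' the study conditions the pipeline is built for: a 13-hydrophone array
#' nominally spaced 70 m apart in a single sheared channel, tags on a 5 s
#' pulse-rate interval with Gaussian ping jitter, piecewise-linear receiver
#' clock drifts up to about half a second, sub-millisecond arrival-time
#' noise, and a small fraction of multipath-like corrupted detections.
#'
#' @param n_receivers Number of hydrophones (>= 3); default 13.
#' @param nominal_spacing Nominal distance between adjacent hydrophones (m);
#'   default 70.
#' @param array_jitter_sd Gaussian placement jitter applied to each
#'   hydrophone coordinate (m); default 0 (regular array).
#' @param pri Tag pulse-rate interval (s); default 5.
#' @param pri_jitter_sd SD of zero-mean Gaussian ping-interval jitter (s);
#'   default 0.1.
#' @param beacon_interval Interval between synchronization pings emitted by
#'   each hydrophone (s); default 30.
#' @param sound_speed Speed of sound in fresh water (m/s); default 1470.
#' @param drift_amplitude Cap on the magnitude of generated piecewise-linear
#'   clock offsets (s); default 0.5.
#' @param drift_knot_interval Spacing of the true drift knots (s); default
#'   21600 (6 h).
#' @param arrival_noise_sd SD of Gaussian arrival-time noise (s); default
#'   2e-4 (0.2 ms).
#' @param detection_prob Per-receiver, per-ping detection probability;
#'   default 0.7.
#' @param corrupt_frac Fraction of detections corrupted by a multipath-like
#'   extra delay; default 0.001.
#' @param corrupt_delay_range Range of the uniform extra delay (s); default
#'   5--50 ms.
#' @param corrupt_mode `"duplicate"` (default) appends a delayed copy of the
#'   affected detection, mimicking a surface/bed reflection arriving after
#'   the direct path; `"delay"` shifts the original detection instead.
#' @param channel Named list describing the channel: `length`, `width`,
#'   `depth` (m), `peak_speed` (m/s at the surface on the centerline),
#'   `roughness_z0` (m), `tidal_amplitude` (m/s), `tidal_period` (s).
#' @param behaviors Data frame with columns `label`, `fraction`,
#'   `swim_speed` (m/s) and `diel` (logical) describing the mix of
#'   prescribed swim behaviors; fractions must sum to 1.
#' @param fork_length_mm Length-2 numeric `c(mean, sd)` of fish fork length
#'   (mm); default `c(76.6, 3)`.
#' @param tag_depth Assumed tag depth below the free surface (m); default 1.
#'
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_receivers = 13,
                            nominal_spacing = 70,
                            array_jitter_sd = 0,
                            pri = 5,
                            pri_jitter_sd = 0.1,
                            beacon_interval = 30,
                            sound_speed = 1470,
                            drift_amplitude = 0.5,
                            drift_knot_interval = 21600,
                            arrival_noise_sd = 2e-4,
                            detection_prob = 0.7,
                            corrupt_frac = 0.001,
                            corrupt_delay_range = c(0.005, 0.050),
                            corrupt_mode = c("duplicate", "delay"),
                            channel = list(),
                            behaviors = NULL,
                            fork_length_mm = c(76.6, 3),
                            tag_depth = 1) {
  corrupt_mode <- match.arg(corrupt_mode)
  chan <- utils::modifyList(
    list(length = 1000, width = 50, depth = 4, peak_speed = 0.5,
         roughness_z0 = 0.003, tidal_amplitude = 0, tidal_period = 44712),
    channel
  )
  if (is.null(behaviors)) {
    behaviors <- tibble::tibble(
      label = c("positive_rheotaxis", "negative_rheotaxis", "lateral", "passive"),
      fraction = c(0.25, 0.25, 0.25, 0.25),
      swim_speed = c(0.10, 0.10, 0.09, 0),
      diel = FALSE
    )
  }
  behaviors <- tibble::as_tibble(behaviors)
  stopifnot(
    n_receivers >= 3,
    pri > 0, pri_jitter_sd >= 0, beacon_interval > 0,
    sound_speed > 0,
    detection_prob >= 0, detection_prob <= 1,
    corrupt_frac >= 0, corrupt_frac < 1,
    length(corrupt_delay_range) == 2, all(corrupt_delay_range > 0),
    chan$depth > 0, chan$roughness_z0 < chan$depth,
    tag_depth > 0, fork_length_mm[1] > 0
  )
  if (abs(sum(behaviors$fraction) - 1) > 1e-8) {
    stop("behavior fractions must sum to 1")
  }
  structure(
    list(n_receivers = n_receivers, nominal_spacing = nominal_spacing,
         array_jitter_sd = array_jitter_sd,
         pri = pri, pri_jitter_sd = pri_jitter_sd,
         beacon_interval = beacon_interval, sound_speed = sound_speed,
         drift_amplitude = drift_amplitude,
         drift_knot_interval = drift_knot_interval,
         arrival_noise_sd = arrival_noise_sd,
         detection_prob = detection_prob,
         corrupt_frac = corrupt_frac,
         corrupt_delay_range = corrupt_delay_range,
         corrupt_mode = corrupt_mode,
         channel = chan, behaviors = behaviors,
         fork_length_mm = fork_length_mm, tag_depth = tag_depth),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$n_receivers, "receivers @", x$nominal_spacing,
      "m, PRI", x$pri, "s, beacons every", x$beacon_interval, "s\n")
  cat("  channel", x$channel$length, "x", x$channel$width, "m, depth",
      x$channel$depth, "m, peak speed", x$channel$peak_speed, "m/s\n")
  cat("  noise sd", format(x$arrival_noise_sd), "s, corrupt",
      format(x$corrupt_frac), "(", x$corrupt_mode, ")\n")
  invisible(x)
}

#' Read a scenario configuration from YAML
#'
#' Convenience loader: top-level YAML keys map onto [scenario_config()]
#' arguments.
#'
#' @param path Path to a YAML file.
#' @return A [scenario_config()].
#' @export
read_scenario <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML scenarios requires the 'yaml' package")
  }
  args <- yaml::read_yaml(path)
  if (!is.null(args$behaviors)) {
    args$behaviors <- dplyr::bind_rows(lapply(args$behaviors, tibble::as_tibble))
  }
  for (nm in c("fork_length_mm", "corrupt_delay_range")) {
    if (!is.null(args[[nm]])) args[[nm]] <- as.numeric(unlist(args[[nm]]))
  }
  do.call(scenario_config, args)
}
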