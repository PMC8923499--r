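#' Run the full synthetic pipeline
#'
#' End-to-end convenience wrapper used for parameter-recovery studies:
#' generates the array, flow field and fish tracks, simulates detections
#' (with optional clock drift and arrival noise), synchronizes clocks,
#' deduplicates multipath, assembles and locates pings, applies the QC
#' cascade, and computes weighted swim records. Every intermediate product
#' is returned so each stage can be scored against the ground truth.
#'
#' @param config A [scenario_config()].
#' @param n_fish Number of fish; default 30.
#' @param duration Field/beacon duration (s); default 7200.
#' @param drift Inject and then estimate clock drifts? Default `TRUE`;
#'   when `FALSE` the clocks are perfect and synchronization is an
#'   identity check.
#' @param vranges Vertical ranges for swim records.
#' @param qc A [qc_config()]; default built around the array footprint.
#' @param knot_interval Sync knot spacing (s); default 3600.
#' @param max_gap Segment gap limit (s); default `4 * config$pri`.
#' @param seed Integer seed controlling every stochastic stage.
#' @return A list: `array`, `field`, `tracks`, `sim` (detections +
#'   truth), `sync`, `fixes`, `qc` (kept fixes + log), `segments`,
#'   `records` (weighted swim records), `reach`, `gauges`.
#' @export
run_synthetic_pipeline <- function(config = scenario_config(),
                                   n_fish = 30, duration = 7200,
                                   drift = TRUE,
                                   vranges = vrange_levels(),
                                   qc = NULL, knot_interval = 3600,
                                   max_gap = NULL, seed = 1) {
  if (is.null(max_gap)) max_gap <- 4 * config$pri
  array <- gen_array(config, seed = seed)
  field <- gen_field(config, duration = duration)
  tracks <- simulate_fish(field, config, n_fish = n_fish, t_max = duration,
                          seed = seed + 1)
  drifts <- if (drift) {
    gen_drifts(array, config, 0, duration, seed = seed + 2)
  } else NULL
  sim <- simulate_detections(tracks, array, config, t_span = c(0, duration),
                             drifts = drifts, seed = seed + 3)
  sync <- solve_sync(sim$detections, array,
                     knot_interval = knot_interval,
                     sound_speed = config$sound_speed)
  corrected <- apply_sync(sim$detections, sync$model)
  tags <- corrected[corrected$source_kind == "tag", ]
  tags <- dedupe_multipath(tags, window = config$pri / 2)
  tags <- assemble_pings(tags, array, sound_speed = config$sound_speed)
  fixes <- locate_pings(tags, array, sound_speed = config$sound_speed,
                        tag_z = -config$tag_depth)
  if (is.null(qc)) {
    pad <- config$nominal_spacing / 2
    region <- cbind(
      x = c(min(array$x) - pad, max(array$x) + pad, max(array$x) + pad,
            min(array$x) - pad, min(array$x) - pad),
      y = c(0, 0, config$channel$width, config$channel$width, 0))
    qc <- qc_config(region = region)
  }
  kept <- qc_tracks(build_tracks(fixes), qc)
  segments <- make_segments(kept$fixes, max_gap = max_gap)
  records <- swim_records(segments, field, vranges = vranges) |>
    segment_weights()
  gauges <- gen_gauges(field, config,
                       times = seq(0, duration, length.out = 49))
  depth <- config$channel$depth
  vol0 <- config$channel$length * config$channel$width * depth
  reach <- river_reach(
    gauges,
    volume_curve = tibble::tibble(
      stage = c(-1, 0, 1),
      volume = vol0 * (depth + c(-1, 0, 1)) / depth),
    La = config$channel$length)
  list(array = array, field = field, tracks = tracks, sim = sim,
       sync = sync, fixes = fixes, qc = kept, segments = segments,
       records = records, reach = reach, gauges = gauges)
}

#' Write / read detection and receiver tables
#'
#' Plain-CSV persistence for the pipeline's tabular interchange formats.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `write_table_csv()` returns `path` invisibly;
#'   `read_table_csv()` returns a tibble.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
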