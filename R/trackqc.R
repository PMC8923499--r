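#' Quality-control configuration
#'
#' Thresholds for the position- and track-level screening cascade:
#' fix-level filters (positional sd, receiver count), endpoint truncation,
#' clipping to the analysis region with an upstream allowance, minimum
#' track length, a residence-time predator rule, and a post-hoc
#' swim-speed predator rule.
#'
#' @param sd_max Maximum positional standard deviation (m); fixes
#'   exceeding it are eliminated. Default 10.
#' @param min_receivers Minimum receivers per fix; default 2.
#' @param endpoint_min_receivers Tracks are truncated to start and end
#'   with fixes using at least this many receivers; default 3.
#' @param min_positions Tracks with fewer retained positions are omitted;
#'   default 10.
#' @param max_residence Tracks resident longer than this (s) are flagged
#'   as likely predators; default 3600.
#' @param upstream_buffer Fixes more than this far upstream (-x) of the
#'   region's upstream edge are eliminated (m); default 30.
#' @param predator_speed Tags with mean swim speed above this (m/s) are
#'   eliminated as likely predators; default 0.5.
#' @param region Analysis-region polygon: a two-column matrix or data
#'   frame of planar `(x, y)` vertices.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(sd_max = 10, min_receivers = 2,
                      endpoint_min_receivers = 3, min_positions = 10,
                      max_residence = 3600, upstream_buffer = 30,
                      predator_speed = 0.5, region = NULL) {
  stopifnot(sd_max > 0, min_receivers > 0, endpoint_min_receivers > 0,
            min_positions > 0, max_residence > 0, upstream_buffer > 0,
            predator_speed > 0)
  if (!is.null(region)) {
    region <- as.matrix(as.data.frame(region)[, 1:2])
    colnames(region) <- c("x", "y")
    if (nrow(region) < 3) stop("region polygon needs at least 3 vertices")
  }
  structure(
    list(sd_max = sd_max, min_receivers = min_receivers,
         endpoint_min_receivers = endpoint_min_receivers,
         min_positions = min_positions, max_residence = max_residence,
         upstream_buffer = upstream_buffer, predator_speed = predator_speed,
         region = region),
    class = "qc_config"
  )
}

#' Read / write an analysis-region polygon as GeoJSON
#'
#' @param path File path.
#' @return `read_region()` returns a two-column vertex matrix;
#'   `write_region()` returns `path` invisibly.
#' @export
read_region <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- if (!is.null(gj$features)) {
    gj$features$geometry        # FeatureCollection
  } else if (!is.null(gj$geometry)) {
    gj$geometry                 # single Feature
  } else {
    gj                          # bare geometry
  }
  coords <- geom$coordinates
  if (is.list(coords) && is.null(dim(coords))) coords <- coords[[1]]
  m <- if (length(dim(coords)) == 3) coords[1, , ] else as.matrix(coords)
  if (ncol(m) != 2) stop("unrecognized GeoJSON polygon structure")
  colnames(m) <- c("x", "y")
  m
}

#' @rdname read_region
#' @param region Two-column vertex matrix.
#' @export
write_region <- function(region, path) {
  region <- as.matrix(region)
  ring <- lapply(seq_len(nrow(region)), function(i) region[i, ])
  gj <- list(type = "Polygon", coordinates = list(ring))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# region membership with the upstream allowance: a point upstream of the
# polygon's upstream (-x) edge by no more than `buffer` counts as inside
# if it falls within the polygon laterally when advanced to that edge.
.in_region <- function(qc, x, y) {
  if (is.null(qc$region)) return(rep(TRUE, length(x)))
  poly <- qc$region
  inside <- mgcv::in.out(poly, cbind(x, y))
  x_up <- min(poly[, "x"])
  near <- !inside & x < x_up & (x_up - x) <= qc$upstream_buffer
  if (any(near)) {
    probe <- cbind(rep(x_up + 1e-6 * max(1, abs(x_up)), sum(near)), y[near])
    inside[near] <- mgcv::in.out(poly, probe)
  }
  inside
}

#' Fix-level QC filter
#'
#' Eliminates fixes whose estimated positional standard deviation exceeds
#' `sd_max` (strictly) or that used fewer than `min_receivers` receivers.
#'
#' @param fixes Fix tibble.
#' @param qc A [qc_config()].
#' @return The surviving fixes, order preserved.
#' @export
filter_fixes <- function(fixes, qc) {
  fixes[!(fixes$sd > qc$sd_max | fixes$n_receivers < qc$min_receivers), ]
}

#' Truncate tracks to well-determined endpoints
#'
#' Drops leading and trailing fixes determined by fewer than
#' `endpoint_min_receivers` receivers; interior fixes are retained
#' regardless of receiver count.
#'
#' @inheritParams filter_fixes
#' @return The truncated fixes.
#' @export
truncate_track <- function(fixes, qc) {
  if (nrow(fixes) == 0) return(fixes)
  fixes |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::group_modify(function(df, key) {
      ok <- which(df$n_receivers >= qc$endpoint_min_receivers)
      if (length(ok) == 0) return(df[0, ])
      df[min(ok):max(ok), ]
    }) |>
    dplyr::ungroup()
}

#' Track-level selection
#'
#' Clips each track to the analysis region (dropping fixes farther than
#' the upstream buffer beyond its upstream edge), then omits tracks with
#' fewer than `min_positions` retained fixes and flags tracks resident in
#' the region longer than `max_residence` as likely predators. Every
#' rejection is logged with its rule name.
#'
#' @inheritParams filter_fixes
#' @return A list: `fixes` (kept) and `log` (tibble `tag_id`, `rule`,
#'   `detail`).
#' @export
select_tracks <- function(fixes, qc) {
  log <- list()
  if (!is.null(qc$region)) {
    inside <- .in_region(qc, fixes$x, fixes$y)
    if (any(!inside)) {
      log$clip <- fixes[!inside, c("tag_id", "t")] |>
        dplyr::count(.data$tag_id, name = "n") |>
        dplyr::mutate(rule = "outside_region",
                      detail = paste(.data$n, "fixes clipped")) |>
        dplyr::select("tag_id", "rule", "detail")
    }
    fixes <- fixes[inside, ]
  }
  counts <- fixes |> dplyr::count(.data$tag_id)
  short <- counts$tag_id[counts$n < qc$min_positions]
  if (length(short) > 0) {
    log$short <- tibble::tibble(tag_id = short, rule = "min_positions",
                                detail = "fewer than min_positions fixes")
    fixes <- fixes[!(fixes$tag_id %in% short), ]
  }
  preds <- character(0)
  if (nrow(fixes) > 0) {
    res <- fixes |>
      dplyr::group_by(.data$tag_id) |>
      dplyr::summarise(residence = max(.data$t) - min(.data$t))
    preds <- res$tag_id[res$residence > qc$max_residence]
  }
  if (length(preds) > 0) {
    log$pred <- tibble::tibble(tag_id = preds, rule = "predator_residence",
                               detail = "residence exceeds max_residence")
    fixes <- fixes[!(fixes$tag_id %in% preds), ]
  }
  list(fixes = fixes,
       log = if (length(log)) dplyr::bind_rows(log) else
         tibble::tibble(tag_id = character(), rule = character(),
                        detail = character()))
}

#' Full position/track QC cascade
#'
#' Applies, in order: fix-level filters, endpoint truncation, region
#' clipping, and the track count/residence rules. The swim-speed predator
#' rule ([flag_predator_by_speed()]) runs separately once swim records
#' exist.
#'
#' @inheritParams filter_fixes
#' @return A list: `fixes` (analysis set) and `log` (rejection log).
#' @export
qc_tracks <- function(fixes, qc) {
  trimmed <- fixes |> filter_fixes(qc) |> truncate_track(qc)
  out <- select_tracks(trimmed, qc)
  gone <- setdiff(unique(fixes$tag_id), unique(trimmed$tag_id))
  if (length(gone) > 0) {
    out$log <- dplyr::bind_rows(
      tibble::tibble(tag_id = gone, rule = "no_valid_fixes",
                     detail = "all fixes failed position-level screening"),
      out$log)
  }
  out
}

#' Swim-speed predator rule
#'
#' Tags whose mean swim speed over all segments exceeds `predator_speed`
#' (strictly) are flagged as likely predators. Tags without swim records
#' get a deferred decision.
#'
#' @param swim_records Swim-record tibble with `tag_id`, `us_u`, `us_v`
#'   (one vertical range, conventionally the top-2 m).
#' @param qc A [qc_config()].
#' @return A tibble `tag_id`, `mean_swim_speed`, `drop`.
#' @export
flag_predator_by_speed <- function(swim_records, qc) {
  if (nrow(swim_records) == 0) {
    return(tibble::tibble(tag_id = character(), mean_swim_speed = numeric(),
                          drop = logical()))
  }
  swim_records |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::summarise(
      mean_swim_speed = mean(sqrt(.data$us_u^2 + .data$us_v^2))) |>
    dplyr::mutate(drop = .data$mean_swim_speed > qc$predator_speed)
}
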