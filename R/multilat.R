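#' Remove multipath duplicate detections
#'
#' Within each (receiver, source) series, a detection arriving within
#' `window` seconds of the previously *retained* detection is assumed to be
#' a reflection off the riverbed or water surface and dropped; the earliest
#' detection of each cluster is always kept.
#'
#' @param detections Detection tibble; times are taken from
#'   `corrected_time` when present, else `raw_time`.
#' @param window Dead time after a retained detection (s).
#' @return The detections with duplicates removed, original order
#'   preserved within groups.
#' @export
dedupe_multipath <- function(detections, window) {
  if (nrow(detections) == 0) return(detections)
  tcol <- if ("corrected_time" %in% names(detections)) "corrected_time" else
    "raw_time"
  tt <- detections[[tcol]]
  grp <- paste(detections$receiver_id, detections$source_id)
  ord <- order(grp, tt)
  keep <- rep(TRUE, length(tt))
  g <- grp[ord]; tv <- tt[ord]
  repeat {
    ki <- which(keep[ord])
    gk <- g[ki]; tk <- tv[ki]
    prev_same <- c(FALSE, gk[-1] == gk[-length(gk)])
    gap <- c(Inf, diff(tk))
    viol <- prev_same & gap < window
    first_of_run <- viol & !c(FALSE, viol[-length(viol)])
    if (!any(first_of_run)) break
    keep[ord[ki[first_of_run]]] <- FALSE
  }
  detections[keep, ]
}

#' Associate detections into transmission events
#'
#' Clusters each source's corrected detection times into pings: two
#' detections join the same group when their corrected times differ by
#' less than the array's maximum propagation delay (maximum pairwise
#' receiver distance over the sound speed). Groups are disjoint; when a
#' receiver appears twice in one group only its earliest detection is
#' retained (the rest are logged in the `collisions` attribute).
#'
#' @param detections Corrected detections (`corrected_time` required).
#' @param array Hydrophone tibble.
#' @param sound_speed Speed of sound (m/s).
#' @param max_delay Optional override of the clustering gap (s).
#' @return The detections with an integer `ping` column.
#' @export
assemble_pings <- function(detections, array, sound_speed = 1470,
                           max_delay = NULL) {
  stopifnot("corrected_time" %in% names(detections))
  if (is.null(max_delay)) {
    pos <- as.matrix(array[, c("x", "y", "z")])
    max_delay <- max(stats::dist(pos)) / sound_speed
  }
  det <- detections[order(detections$source_id, detections$corrected_time), ]
  new_grp <- c(TRUE, diff(det$corrected_time) >= max_delay |
                 det$source_id[-1] != det$source_id[-nrow(det)])
  det$ping <- cumsum(new_grp)
  dup <- duplicated(det[, c("ping", "receiver_id")])
  collisions <- det[dup, ]
  det <- det[!dup, ]
  attr(det, "collisions") <- collisions
  det
}

# Gauss-Newton solution of one ping: minimize over (x, y, T) the sum of
# squared arrival residuals t_h - T - d_h(x, y)/c, with tag depth fixed.
.gn_locate <- function(tt, rx, ry, rz, sound_speed, init, tag_z,
                       max_iter = 50, tol = 1e-6, max_range = 1000) {
  p <- init
  Tt <- min(tt) - 0.01
  conv <- FALSE
  J <- matrix(0, length(tt), 3)
  for (it in seq_len(max_iter)) {
    dx <- p[1] - rx; dy <- p[2] - ry; dz <- tag_z - rz
    d <- sqrt(dx^2 + dy^2 + dz^2)
    d <- pmax(d, 1e-6)
    r <- tt - Tt - d / sound_speed
    J[, 1] <- dx / (sound_speed * d)
    J[, 2] <- dy / (sound_speed * d)
    J[, 3] <- 1
    JtJ <- crossprod(J)
    step <- tryCatch(solve(JtJ, crossprod(J, r)), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    p <- p + step[1:2]
    Tt <- Tt + step[3]
    if (sqrt(sum(step[1:2]^2)) < tol) { conv <- TRUE; break }
  }
  if (!conv) return(NULL)
  if (sqrt(sum((p - init)^2)) > max_range &&
      sqrt((p[1] - mean(rx))^2 + (p[2] - mean(ry))^2) > max_range) {
    return(NULL)
  }
  dxy <- sqrt((p[1] - rx)^2 + (p[2] - ry)^2 + (tag_z - rz)^2)
  r <- tt - Tt - dxy / sound_speed
  sigma2 <- sum(r^2) / max(length(tt) - 3, 1)
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  sd <- if (is.null(cov)) NA_real_ else sqrt(mean(diag(cov)[1:2]))
  list(x = p[1], y = p[2], t = Tt, sd = sd, n = length(tt))
}

#' Locate a single ping
#'
#' Estimates a 2-D tag position and emission time from one group of
#' corrected arrival times by Gauss-Newton minimization of
#' `sum((t_h - T - d_h(x, y)/c)^2)`. The tag's depth is fixed (vertical
#' position is unobservable with a near-planar array); receiver depths
#' enter the slant ranges. The reported `sd` is the square root of the
#' mean diagonal of the linearized position covariance scaled by the
#' residual variance.
#'
#' @param group Tibble with `receiver_id` and `corrected_time` for one
#'   ping (distinct receivers).
#' @param array Hydrophone tibble.
#' @param sound_speed Speed of sound (m/s).
#' @param init Optional initial `(x, y)`; defaults to the array centroid.
#' @param tag_z Assumed tag elevation (m, same datum as receiver `z`);
#'   default -1 (1 m below a surface at 0).
#' @param max_range Fixes farther than this from the array are rejected
#'   (m).
#' @return A one-row tibble `t`, `x`, `y`, `sd`, `n_receivers`, or `NULL`
#'   when the group has fewer than 3 receivers or the solver fails.
#' @export
locate_ping <- function(group, array, sound_speed = 1470, init = NULL,
                        tag_z = -1, max_range = 1000) {
  idx <- match(group$receiver_id, array$id)
  if (anyNA(idx)) stop("group references unknown receivers")
  if (length(unique(group$receiver_id)) < 3) return(NULL)
  if (is.null(init)) init <- c(mean(array$x), mean(array$y))
  fit <- .gn_locate(group$corrected_time, array$x[idx], array$y[idx],
                    array$z[idx], sound_speed, init, tag_z,
                    max_range = max_range)
  if (is.null(fit)) return(NULL)
  tibble::tibble(t = fit$t, x = fit$x, y = fit$y, sd = fit$sd,
                 n_receivers = fit$n)
}

#' Locate all pings of a detection table
#'
#' Runs [locate_ping()] over every assembled ping group, initializing each
#' solve from the tag's previous fix when it is less than 60 s old and
#' from the array centroid otherwise. Groups with fewer than 3 receivers
#' are counted but not located; failed solves are logged.
#'
#' @param detections Output of [assemble_pings()] (tag detections with
#'   `ping` ids).
#' @param array Hydrophone tibble.
#' @inheritParams locate_ping
#' @param reuse_window Age limit for initializing from the previous fix
#'   (s); default 60.
#' @return A tibble of position fixes (`tag_id`, `t`, `x`, `y`, `sd`,
#'   `n_receivers`) with a `skipped` attribute summarizing unlocated
#'   groups.
#' @export
locate_pings <- function(detections, array, sound_speed = 1470, tag_z = -1,
                         max_range = 1000, reuse_window = 60) {
  stopifnot("ping" %in% names(detections))
  centroid <- c(mean(array$x), mean(array$y))
  pos_idx <- stats::setNames(seq_len(nrow(array)), array$id)
  ord <- order(detections$source_id, detections$corrected_time)
  det <- detections[ord, ]
  groups <- split(seq_len(nrow(det)), det$ping)
  first_rows <- vapply(groups, `[`, integer(1), 1)
  groups <- groups[order(det$corrected_time[first_rows])]
  fixes <- vector("list", length(groups))
  skipped <- integer(0)
  few <- 0L
  last_fix <- list()
  for (k in seq_along(groups)) {
    rows <- groups[[k]]
    tag <- det$source_id[rows[1]]
    rid <- det$receiver_id[rows]
    if (length(unique(rid)) < 3) { few <- few + 1L; next }
    idx <- pos_idx[rid]
    prev <- last_fix[[tag]]
    init <- if (!is.null(prev) &&
                min(det$corrected_time[rows]) - prev$t < reuse_window) {
      c(prev$x, prev$y)
    } else centroid
    fit <- .gn_locate(det$corrected_time[rows], array$x[idx], array$y[idx],
                      array$z[idx], sound_speed, init, tag_z,
                      max_range = max_range)
    if (is.null(fit)) { skipped <- c(skipped, det$ping[rows[1]]); next }
    fixes[[k]] <- tibble::tibble(tag_id = tag, t = fit$t, x = fit$x,
                                 y = fit$y, sd = fit$sd, n_receivers = fit$n)
    last_fix[[tag]] <- fit
  }
  out <- dplyr::bind_rows(fixes)
  attr(out, "skipped") <- list(failed_pings = skipped, under_3_receivers = few)
  out
}

#' Order fixes into tracks
#'
#' Groups fixes by tag and time-sorts them; fixes sharing a timestamp are
#' collapsed to the one with the smaller positional `sd`.
#'
#' @param fixes Fix tibble (`tag_id`, `t`, `x`, `y`, `sd`, `n_receivers`).
#' @return The ordered fix tibble.
#' @export
build_tracks <- function(fixes) {
  if (nrow(fixes) == 0) return(fixes)
  fixes |>
    dplyr::arrange(.data$tag_id, .data$t, .data$sd) |>
    dplyr::distinct(.data$tag_id, .data$t, .keep_all = TRUE)
}
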