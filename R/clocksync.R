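#' Build the linear clock-synchronization system
#'
#' With receiver positions fixed, clock synchronization reduces to a sparse
#' linear least-squares problem. Each beacon detection contributes one
#' equation
#' \deqn{raw\_time - d(source, receiver)/c = T_k + \sum_j w_j(t)\,
#'   \theta_{receiver, j},}
#' with unknowns the per-ping emission times `T_k` and the knot values
#' `theta` of each receiver's continuous piecewise-linear clock-offset
#' function on a shared regular knot grid. The reference receiver's offset
#' is fixed at zero (gauge fixing), so its `theta` columns are excluded;
#' every remaining row has at most two nonzeros beyond its `T_k` column
#' (the hat-function weights bracketing the detection time).
#'
#' Detections are associated to transmission events by clustering each
#' source's detection times with a gap threshold comfortably larger than
#' the array's maximum propagation delay plus the drift scale.
#'
#' @param detections Tibble of beacon detections (`det_id`, `receiver_id`,
#'   `source_id`, `raw_time`); every `source_id` must be a receiver in
#'   `array`.
#' @param array Hydrophone tibble (`id`, `x`, `y`, `z`, `role`) with
#'   exactly one `role == "reference"` row.
#' @param knot_interval Knot spacing of the offset functions (s).
#' @param window Length-2 numeric `[t0, t1]`: only detections in this span
#'   enter the system.
#' @param sound_speed Speed of sound (m/s); default 1470.
#' @param group_gap Gap threshold for associating detections to pings (s);
#'   default `2 * max_propagation_delay + 1.2`.
#' @return A list: sparse design `A`, response `y`, retained detections
#'   `det` (with `group` ids), `knots`, `theta_cols` (receiver/knot to
#'   column map), `n_groups`, and the reference receiver id.
#' @export
build_sync_system <- function(detections, array, knot_interval,
                              window = NULL, sound_speed = 1470,
                              group_gap = NULL) {
  ref <- array$id[array$role == "reference"]
  if (length(ref) != 1) stop("array must contain exactly one reference receiver")
  det <- detections[detections$source_id %in% array$id, ]
  if (is.null(window)) window <- range(det$raw_time)
  det <- det[det$raw_time >= window[1] & det$raw_time <= window[2], ]
  if (nrow(det) == 0) stop("window contains no beacon detections")
  if (!all(det$receiver_id %in% array$id)) {
    stop("detections reference receivers missing from the array")
  }
  pos <- as.matrix(array[, c("x", "y", "z")])
  rownames(pos) <- array$id
  dmax <- max(stats::dist(pos))
  if (is.null(group_gap)) group_gap <- 2 * dmax / sound_speed + 1.2

  # travel-time-corrected receive times
  d <- sqrt(rowSums((pos[det$source_id, , drop = FALSE] -
                       pos[det$receiver_id, , drop = FALSE])^2))
  y <- det$raw_time - d / sound_speed

  # cluster per source into transmission events
  det$y <- y
  det <- det[order(det$source_id, det$y), ]
  new_grp <- c(TRUE, diff(det$y) > group_gap |
                 det$source_id[-1] != det$source_id[-nrow(det)])
  det$group <- cumsum(new_grp)

  # connectivity: receivers must reach the reference through shared pings
  inc <- unique(det[, c("receiver_id", "group")])
  reached <- ref
  repeat {
    grps <- unique(inc$group[inc$receiver_id %in% reached])
    nxt <- unique(inc$receiver_id[inc$group %in% grps])
    if (all(nxt %in% reached)) break
    reached <- union(reached, nxt)
  }
  orphan <- setdiff(unique(det$receiver_id), reached)
  if (length(orphan) > 0) {
    stop("receivers not connected to the reference via shared pings: ",
         paste(orphan, collapse = ", "))
  }

  # interior knots on the absolute `knot_interval` grid, end knots snapped
  # to the first/last detection: the grid covers the data exactly, the end
  # knots always carry the extreme detections at full hat weight (so they
  # are well determined), and interior knots stay aligned across windows
  dspan <- range(det$raw_time)
  lo <- ceiling(dspan[1] / knot_interval + 1e-9) * knot_interval
  hi <- floor(dspan[2] / knot_interval - 1e-9) * knot_interval
  interior <- if (lo <= hi) seq(lo, hi, by = knot_interval) else numeric(0)
  knots <- c(dspan[1], interior, dspan[2])
  if (length(knots) < 2) knots <- c(dspan[1], dspan[1] + knot_interval)
  nonref <- setdiff(array$id, ref)
  theta_cols <- tidyr::expand_grid(receiver_id = nonref, knot = seq_along(knots))
  theta_cols$knot_time <- knots[theta_cols$knot]
  theta_cols$col <- seq_len(nrow(theta_cols))

  n <- nrow(det)
  K <- max(det$group)
  # hat weights for each detection on its receiver's knots
  aw <- .axis_weights(knots, pmin(pmax(det$raw_time, knots[1]),
                                  knots[length(knots)]))
  keymap <- stats::setNames(theta_cols$col,
                            paste(theta_cols$receiver_id, theta_cols$knot))
  is_nonref <- det$receiver_id != ref
  c1 <- keymap[paste(det$receiver_id, aw$i)]
  c2 <- keymap[paste(det$receiver_id, aw$i + 1L)]
  ii <- c(seq_len(n), which(is_nonref), which(is_nonref))
  jj <- c(det$group, K + c1[is_nonref], K + c2[is_nonref])
  xx <- c(rep(1, n), (1 - aw$w)[is_nonref], aw$w[is_nonref])
  keep <- !is.na(jj)
  A <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                            dims = c(n, K + nrow(theta_cols)))
  list(A = A, y = det$y, det = det, knots = knots, theta_cols = theta_cols,
       n_groups = K, ref = ref, window = window)
}

# Solve one assembled system for theta by eliminating the emission times
# through per-ping centering (the Schur complement of the block-diagonal
# T block). Returns theta, per-detection residuals and emission times.
.solve_centered <- function(sys) {
  det <- sys$det
  n <- nrow(det)
  P <- nrow(sys$theta_cols)
  K <- max(det$group)
  aw <- .axis_weights(sys$knots, pmin(pmax(det$raw_time, sys$knots[1]),
                                      sys$knots[length(sys$knots)]))
  keymap <- stats::setNames(sys$theta_cols$col,
                            paste(sys$theta_cols$receiver_id, sys$theta_cols$knot))
  is_nonref <- det$receiver_id != sys$ref
  c1 <- keymap[paste(det$receiver_id, aw$i)]
  c2 <- keymap[paste(det$receiver_id, aw$i + 1L)]
  ii <- c(which(is_nonref), which(is_nonref))
  jj <- c(c1[is_nonref], c2[is_nonref])
  xx <- c((1 - aw$w)[is_nonref], aw$w[is_nonref])
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, P))
  G <- Matrix::sparseMatrix(i = seq_len(n), j = det$group, x = 1,
                            dims = c(n, K))
  yv <- det$y
  ng <- Matrix::colSums(G)
  Wbar <- Matrix::Diagonal(x = 1 / ng) %*% Matrix::crossprod(G, W)
  ybar <- as.vector(Matrix::crossprod(G, yv)) / ng
  M <- Matrix::crossprod(W) - Matrix::crossprod(Wbar, Matrix::Diagonal(x = ng) %*% Wbar)
  b <- as.vector(Matrix::crossprod(W, yv)) -
    as.vector(Matrix::crossprod(Wbar, ng * ybar))
  dg <- Matrix::diag(M)
  live <- which(dg > 1e-10)
  theta <- rep(0, P)
  if (length(live) > 0) {
    Ml <- M[live, live, drop = FALSE]
    sol <- tryCatch(
      as.vector(Matrix::solve(Ml, b[live])),
      error = function(e) {
        # rank deficiency: fall back to a tiny ridge and report
        as.vector(Matrix::solve(Ml + Matrix::Diagonal(length(live)) * 1e-8,
                                b[live]))
      })
    theta[live] <- sol
  }
  r <- yv - as.vector(W %*% theta)
  Tk <- as.vector(Matrix::crossprod(G, r)) / ng
  resid <- r - Tk[det$group]
  list(theta = theta, resid = resid, Tk = Tk, supported = seq_len(P) %in% live)
}

#' Estimate clock offsets by iterative sparse least squares
#'
#' Solves the linear system of [build_sync_system()] window by window.
#' Within each window the solver iterates: solve the sparse least-squares
#' problem, and while the RMS residual of retained detections exceeds
#' `rms_threshold`, remove the single detection with the largest absolute
#' residual and solve again. Iteration also stops at a removal cap
#' (`max(0.5%` of detections`, 100)` by default), in which case the window
#' is flagged unsuccessful. Before solving, multipath duplicates (repeat
#' receptions of one ping on one receiver within `dedupe_window`) are
#' dropped and recorded as removed with reason `"multipath"`.
#'
#' @inheritParams build_sync_system
#' @param rms_threshold Stopping threshold on the RMS residual (s); default
#'   1e-3 (1 ms).
#' @param window_len Length of independently solved periods (s); default 5
#'   days.
#' @param removal_cap Maximum worst-residual removals per window; default
#'   `max(0.005 * n, 100)`.
#' @param dedupe_window Window for the multipath pre-pass (s); default 1.
#'   Set to 0 to disable.
#' @return A `sync_fit`: `model` (clock-offset knot table), `removed`
#'   (detections dropped, with residuals and reasons), `rms_residual`,
#'   `n_iterations`, `success`, and a per-window summary.
#' @export
solve_sync <- function(detections, array, knot_interval = 3600,
                       rms_threshold = 1e-3, window_len = 5 * 86400,
                       sound_speed = 1470, removal_cap = NULL,
                       dedupe_window = 1, group_gap = NULL) {
  det <- detections
  if ("source_kind" %in% names(det)) det <- det[det$source_kind == "beacon", ]
  if (nrow(det) == 0) stop("no beacon detections to synchronize on")
  removed <- list()
  if (dedupe_window > 0) {
    deduped <- dedupe_multipath(det, window = dedupe_window)
    dropped <- det[!(det$det_id %in% deduped$det_id), ]
    if (nrow(dropped) > 0) {
      removed$multipath <- tibble::tibble(
        det_id = dropped$det_id, window = NA_integer_,
        residual = NA_real_, reason = "multipath")
    }
    det <- deduped
  }
  t0 <- min(det$raw_time); t1 <- max(det$raw_time)
  n_win <- max(1, ceiling((t1 - t0) / window_len))
  bounds <- t0 + (0:n_win) * (t1 - t0) / n_win
  bounds[n_win + 1] <- bounds[n_win + 1] + 1e-6
  models <- list()
  win_summary <- list()
  rms_paths <- list()
  for (w in seq_len(n_win)) {
    dw <- det[det$raw_time >= bounds[w] & det$raw_time < bounds[w + 1], ]
    sys <- build_sync_system(dw, array, knot_interval,
                             window = c(bounds[w], bounds[w + 1]),
                             sound_speed = sound_speed, group_gap = group_gap)
    cap <- if (is.null(removal_cap)) max(ceiling(0.005 * nrow(sys$det)), 100) else
      removal_cap
    iter <- 0L
    rem_id <- integer(); rem_res <- numeric(); rms_seq <- numeric()
    repeat {
      fit <- .solve_centered(sys)
      rms <- sqrt(mean(fit$resid^2))
      rms_seq <- c(rms_seq, rms)
      if (rms <= rms_threshold || iter >= cap || nrow(sys$det) <= 1) break
      worst <- which.max(abs(fit$resid))
      rem_id <- c(rem_id, sys$det$det_id[worst])
      rem_res <- c(rem_res, fit$resid[worst])
      sys$det <- sys$det[-worst, ]
      iter <- iter + 1L
    }
    success <- rms <= rms_threshold
    tc <- sys$theta_cols
    nonref_tbl <- tibble::tibble(
      receiver_id = tc$receiver_id, knot_time = tc$knot_time,
      offset = fit$theta[tc$col], supported = fit$supported[tc$col])
    # a receiver's offset is identifiable only where it has detections;
    # unsupported (typically edge) knots are filled by flat extension from
    # the nearest supported knot, matching the flat-extrapolation rule
    nonref_tbl <- nonref_tbl |>
      dplyr::group_by(.data$receiver_id) |>
      dplyr::group_modify(function(df, key) {
        sup <- which(df$supported)
        if (length(sup) == 1 && any(!df$supported)) {
          df$offset[!df$supported] <- df$offset[sup]
        } else if (length(sup) > 1 && any(!df$supported)) {
          df$offset[!df$supported] <- stats::approx(
            df$knot_time[sup], df$offset[sup],
            xout = df$knot_time[!df$supported], rule = 2)$y
        }
        df
      }) |>
      dplyr::ungroup()
    model_w <- dplyr::bind_rows(
      nonref_tbl,
      tibble::tibble(receiver_id = sys$ref, knot_time = sys$knots,
                     offset = 0, supported = TRUE)
    )
    model_w$window <- w
    models[[w]] <- model_w
    if (length(rem_id) > 0) {
      removed[[paste0("win", w)]] <- tibble::tibble(
        det_id = rem_id, window = w, residual = rem_res, reason = "residual")
    }
    win_summary[[w]] <- tibble::tibble(
      window = w, t0 = bounds[w], t1 = bounds[w + 1],
      n_detections = nrow(dw), n_retained = nrow(sys$det),
      n_pings = sys$n_groups, n_removed = iter,
      rms_residual = rms, success = success)
    rms_paths[[w]] <- rms_seq
  }
  model <- dplyr::bind_rows(models)
  windows <- dplyr::bind_rows(win_summary)
  structure(
    list(
      model = structure(model, class = c("clock_model", class(model)),
                        windows = windows[, c("window", "t0", "t1")],
                        reference = array$id[array$role == "reference"]),
      removed = if (length(removed)) dplyr::bind_rows(removed) else
        tibble::tibble(det_id = integer(), window = integer(),
                       residual = numeric(), reason = character()),
      rms_residual = sqrt(stats::weighted.mean(windows$rms_residual^2,
                                               windows$n_retained)),
      n_iterations = sum(windows$n_removed),
      success = all(windows$success),
      windows = windows,
      rms_paths = rms_paths
    ),
    class = "sync_fit"
  )
}

#' @export
print.sync_fit <- function(x, ...) {
  cat("<sync_fit>", nrow(x$windows), "window(s), RMS residual",
      format(x$rms_residual * 1000, digits = 3), "ms,",
      x$n_iterations, "detections removed,",
      if (x$success) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname solve_sync
#' @param x A `sync_fit`.
#' @param ... Unused.
#' @method tidy sync_fit
#' @export
tidy.sync_fit <- function(x, ...) {
  tibble::as_tibble(x$model)
}

#' @rdname solve_sync
#' @method glance sync_fit
#' @export
glance.sync_fit <- function(x, ...) {
  tibble::tibble(
    rms_residual = x$rms_residual,
    n_iterations = x$n_iterations,
    n_windows = nrow(x$windows),
    n_removed = nrow(x$removed),
    success = x$success
  )
}

# Evaluate a clock model's offset for given receivers/times (linear between
# knots, flat beyond the end knots; window chosen by time).
.model_offsets <- function(model, receiver_id, t) {
  wins <- attr(model, "windows")
  out <- rep(NA_real_, length(t))
  wi <- findInterval(t, c(wins$t0[1], wins$t1))
  wi <- pmin(pmax(wi, 1L), nrow(wins))
  for (w in unique(wi)) {
    mw <- model[model$window == w, ]
    sel <- wi == w
    out[sel] <- .eval_offsets(
      tibble::tibble(receiver_id = mw$receiver_id, knot_time = mw$knot_time,
                     offset = mw$offset),
      receiver_id[sel], t[sel])
  }
  out
}

#' Apply a clock model to detections
#'
#' Fills `corrected_time = raw_time - offset(receiver, raw_time)`, with the
#' offset interpolated linearly between knots and held flat beyond the end
#' knots. Detections from receivers absent from the model are dropped and
#' reported in the `rejected` attribute.
#'
#' @param detections Detection tibble with `receiver_id` and `raw_time`.
#' @param model A `clock_model` (from [solve_sync()]'s `$model`) or a plain
#'   knot table `receiver_id`, `knot_time`, `offset`.
#' @return The detections with a `corrected_time` column, per-receiver
#'   order preserved.
#' @export
apply_sync <- function(detections, model) {
  if (inherits(model, "sync_fit")) model <- model$model
  known <- unique(model$receiver_id)
  bad <- !(detections$receiver_id %in% known)
  rejected <- detections[bad, ]
  if (any(bad)) {
    message("apply_sync: dropping ", sum(bad),
            " detection(s) from unknown receivers")
  }
  det <- detections[!bad, ]
  off <- if (inherits(model, "clock_model") && !is.null(attr(model, "windows"))) {
    .model_offsets(model, det$receiver_id, det$raw_time)
  } else {
    .eval_offsets(model, det$receiver_id, det$raw_time)
  }
  det$corrected_time <- det$raw_time - off
  attr(det, "rejected") <- rejected
  det
}
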