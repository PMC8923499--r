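#' Gridded hydrodynamic velocity field
#'
#' A `flow_field` holds horizontal water velocities `u` (along-channel,
#' positive downstream) and `v` (cross-channel) on a rectilinear grid in
#' `(x, y, z, t)`, together with the bed elevation `bed(x, y)` and the free
#' surface `surface(x, y, t)`. Coordinates are local planar meters with `z`
#' positive up; time is seconds. Velocities are defined on wet cells only;
#' queries above the surface or below the bed are clipped to the wetted
#' column, and queries at dry or out-of-grid horizontal locations are
#' rejected (or return `NA` when `strict = FALSE`).
#'
#' @param x,y,z,t Strictly increasing numeric coordinate vectors (any may
#'   have length 1 for a degenerate dimension).
#' @param u,v Numeric arrays of dimension `c(length(x), length(y), length(z),
#'   length(t))`; scalars are recycled. `v` defaults to zero.
#' @param bed Bed elevation: scalar or `length(x) x length(y)` matrix (m).
#' @param surface Free-surface elevation: scalar, `length(x) x length(y)`
#'   matrix, or array with a trailing time dimension (m).
#'
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(x, y, z, t = 0, u, v = 0, bed = NULL, surface = 0) {
  for (nm in c("x", "y", "z", "t")) {
    g <- get(nm)
    if (anyNA(g) || is.unsorted(g, strictly = TRUE)) {
      stop("coordinate `", nm, "` must be strictly increasing and finite")
    }
  }
  dm <- c(length(x), length(y), length(z), length(t))
  expand <- function(a, what) {
    if (length(a) == 1) a <- array(a, dm)
    a <- as.array(a)
    if (!identical(dim(a), as.integer(dm))) {
      stop("`", what, "` must have dim (nx, ny, nz, nt)")
    }
    a
  }
  u <- expand(u, "u")
  v <- expand(v, "v")
  if (is.null(bed)) bed <- min(z)
  if (length(bed) == 1) bed <- matrix(bed, dm[1], dm[2])
  surf <- surface
  if (length(surf) == 1) surf <- array(surf, c(dm[1], dm[2], dm[4]))
  if (length(dim(surf)) == 2) surf <- array(surf, c(dm[1], dm[2], dm[4]))
  if (any(surf <= rep(bed, dm[4]))) {
    stop("surface must lie above bed everywhere (no dry columns supported in-grid)")
  }
  structure(
    list(x = x, y = y, z = z, t = t, u = u, v = v,
         bed = bed, surface = surf),
    class = "flow_field"
  )
}

#' @export
print.flow_field <- function(x, ...) {
  cat("<flow_field> grid",
      length(x$x), "x", length(x$y), "x", length(x$z), "x", length(x$t),
      "(x,y,z,t)\n")
  cat("  x:", format(range(x$x)), " y:", format(range(x$y)),
      " z:", format(range(x$z)), " t:", format(range(x$t)), "\n")
  cat("  speed range:", format(range(sqrt(x$u^2 + x$v^2))), "m/s\n")
  invisible(x)
}

# Interpolation weights along one coordinate axis. Returns lower index and
# the weight of the *upper* node; queries outside the grid get NA unless the
# axis is degenerate (length 1).
.axis_weights <- function(grid, q) {
  n <- length(grid)
  if (n == 1L) {
    return(list(i = rep(1L, length(q)), w = rep(0, length(q)),
                ok = rep(TRUE, length(q))))
  }
  i <- findInterval(q, grid)
  ok <- !is.na(q) & q >= grid[1] & q <= grid[n]
  i[!ok] <- 1L
  i <- pmin(pmax(i, 1L), n - 1L)
  w <- (q - grid[i]) / (grid[i + 1L] - grid[i])
  w[!ok] <- 0
  list(i = i, w = pmin(pmax(w, 0), 1), ok = ok)
}

# Interpolate a (x, y, t) surface-like array (nx x ny x nt) at points.
.interp_xyt <- function(arr, field, x, y, t) {
  ax <- .axis_weights(field$x, x)
  ay <- .axis_weights(field$y, y)
  at <- .axis_weights(field$t, t)
  nx <- length(field$x); ny <- length(field$y)
  out <- numeric(length(x))
  for (cx in 0:1) for (cy in 0:1) for (ct in 0:1) {
    w <- (if (cx) ax$w else 1 - ax$w) *
      (if (cy) ay$w else 1 - ay$w) *
      (if (ct) at$w else 1 - at$w)
    ix <- pmin(ax$i + cx, nx); iy <- pmin(ay$i + cy, ny)
    it <- pmin(at$i + ct, length(field$t))
    idx <- ix + nx * (iy - 1L + ny * (it - 1L))
    out <- out + w * arr[idx]
  }
  out[!(ax$ok & ay$ok & at$ok)] <- NA_real_
  out
}

# Vertical profiles of u and v at query points: trilinear interpolation in
# (x, y, t) at every z level. Returns list(u, v): n x nz matrices.
.interp_profiles <- function(field, x, y, t) {
  ax <- .axis_weights(field$x, x)
  ay <- .axis_weights(field$y, y)
  at <- .axis_weights(field$t, t)
  nx <- length(field$x); ny <- length(field$y)
  nz <- length(field$z); nt <- length(field$t)
  n <- length(x)
  up <- matrix(0, n, nz)
  vp <- matrix(0, n, nz)
  zoff <- nx * ny * (seq_len(nz) - 1L)
  for (cx in 0:1) for (cy in 0:1) for (ct in 0:1) {
    w <- (if (cx) ax$w else 1 - ax$w) *
      (if (cy) ay$w else 1 - ay$w) *
      (if (ct) at$w else 1 - at$w)
    ix <- pmin(ax$i + cx, nx); iy <- pmin(ay$i + cy, ny)
    it <- pmin(at$i + ct, nt)
    base <- ix + nx * (iy - 1L) + nx * ny * nz * (it - 1L)
    # as.vector: a matrix index with ncol == 4 would otherwise be taken as
    # per-dimension subscripts of the 4-d array
    idx <- as.vector(outer(base, zoff, `+`))
    up <- up + w * matrix(field$u[idx], n, nz)
    vp <- vp + w * matrix(field$v[idx], n, nz)
  }
  bad <- !(ax$ok & ay$ok & at$ok)
  up[bad, ] <- NA_real_
  vp[bad, ] <- NA_real_
  list(u = up, v = vp)
}

# Mean of a piecewise-linear profile f(zgrid) over [zlo, zhi], clipping to
# the grid span; zero-thickness slabs fall back to point evaluation.
.slab_means <- function(zgrid, fmat, zlo, zhi) {
  n <- nrow(fmat)
  out <- numeric(n)
  interp1 <- function(zq, fz) {
    a <- .axis_weights(zgrid, zq)
    fz[a$i] * (1 - a$w) + fz[pmin(a$i + 1L, length(zgrid))] * a$w
  }
  for (k in seq_len(n)) {
    fz <- fmat[k, ]
    if (anyNA(fz)) { out[k] <- NA_real_; next }
    lo <- max(zlo[k], zgrid[1]); hi <- min(zhi[k], zgrid[length(zgrid)])
    if (hi - lo <= .Machine$double.eps^0.5) {
      out[k] <- interp1(mean(c(lo, hi)), fz)
      next
    }
    inner <- zgrid[zgrid > lo & zgrid < hi]
    zz <- c(lo, inner, hi)
    ff <- c(interp1(lo, fz), fz[zgrid > lo & zgrid < hi], interp1(hi, fz))
    out[k] <- sum(diff(zz) * (head(ff, -1) + ff[-1]) / 2) / (hi - lo)
  }
  out
}

#' Vertical averaging ranges
#'
#' Fish vertical distribution is unobserved; velocities are therefore
#' referenced to one of three assumed distributions: uniform over the top
#' 1 m of the water column (`"top1m"`), uniform over the top 2 m
#' (`"top2m"`), or uniform from surface to bed (`"full"`).
#'
#' @param vrange Character, one of `"top1m"`, `"top2m"`, `"full"`.
#' @return The matched vrange string.
#' @export
vrange_levels <- function() c("top1m", "top2m", "full")

.vrange_depth <- function(vrange) {
  switch(match.arg(vrange, vrange_levels()),
         top1m = 1, top2m = 2, full = Inf)
}

#' Extract vertically averaged velocity from a flow field
#'
#' Linearly interpolates the gridded field in `x`, `y` and `t`, then
#' averages the vertical velocity profile uniformly over a slab measured
#' down from the instantaneous free surface: the top 1 m, top 2 m, or the
#' full water column. Where the local depth is shallower than the slab, the
#' average is taken over the available depth.
#'
#' @param field A [flow_field()].
#' @param x,y Query coordinates (m), vectorized.
#' @param t Query times (s), scalar or vectorized.
#' @param vrange Vertical averaging range, see [vrange_levels()].
#' @param strict If `TRUE` (default) dry or out-of-grid queries raise an
#'   error echoing the offending location; if `FALSE` they yield `NA`.
#'
#' @return A tibble with columns `u`, `v` (m/s), one row per query point.
#' @export
extract_velocity <- function(field, x, y, t, vrange = "full", strict = TRUE) {
  stopifnot(inherits(field, "flow_field"))
  n <- max(length(x), length(y), length(t))
  x <- rep_len(x, n); y <- rep_len(y, n); t <- rep_len(t, n)
  surf <- .interp_xyt(field$surface, field, x, y, t)
  bed <- .interp_xyt(array(field$bed, c(dim(field$bed), length(field$t))),
                     field, x, y, t)
  rng <- .vrange_depth(vrange)
  zhi <- surf
  zlo <- pmax(bed, surf - rng)
  prof <- .interp_profiles(field, x, y, t)
  u <- .slab_means(field$z, prof$u, zlo, zhi)
  v <- .slab_means(field$z, prof$v, zlo, zhi)
  bad <- is.na(u) | is.na(v)
  if (strict && any(bad)) {
    k <- which(bad)[1]
    stop(sprintf(
      "dry or out-of-grid query at (x=%.2f, y=%.2f, t=%.2f)", x[k], y[k], t[k]))
  }
  tibble::tibble(u = u, v = v)
}

#' Local water depth
#'
#' Instantaneous depth, `surface(x, y, t) - bed(x, y)`, with bilinear
#' interpolation off grid nodes.
#'
#' @inheritParams extract_velocity
#' @return Numeric vector of depths (m).
#' @export
local_depth <- function(field, x, y, t, strict = TRUE) {
  stopifnot(inherits(field, "flow_field"))
  n <- max(length(x), length(y), length(t))
  x <- rep_len(x, n); y <- rep_len(y, n); t <- rep_len(t, n)
  surf <- .interp_xyt(field$surface, field, x, y, t)
  bed <- .interp_xyt(array(field$bed, c(dim(field$bed), length(field$t))),
                     field, x, y, t)
  d <- surf - bed
  if (strict && anyNA(d)) {
    k <- which(is.na(d))[1]
    stop(sprintf("dry or out-of-grid query at (x=%.2f, y=%.2f)", x[k], y[k]))
  }
  d
}

#' Vertical vorticity of the horizontal flow
#'
#' The vertical component of the curl, `dv/dx - du/dy` (effectively the
#' lateral shear), evaluated by central differences of the linearly
#' interpolated, vertically averaged field over a stencil of half-width `h`.
#' All four stencil points must be wet; there is no one-sided fallback.
#'
#' @inheritParams extract_velocity
#' @param h Stencil half-spacing (m); default 2 m, the lateral grid scale of
#'   typical channel-resolving hydrodynamic models.
#' @return Numeric vector of vorticities (1/s).
#' @export
vorticity <- function(field, x, y, t, vrange = "full", h = 2, strict = TRUE) {
  vxp <- extract_velocity(field, x + h, y, t, vrange, strict = FALSE)
  vxm <- extract_velocity(field, x - h, y, t, vrange, strict = FALSE)
  vyp <- extract_velocity(field, x, y + h, t, vrange, strict = FALSE)
  vym <- extract_velocity(field, x, y - h, t, vrange, strict = FALSE)
  w <- (vxp$v - vxm$v) / (2 * h) - (vyp$u - vym$u) / (2 * h)
  if (strict && anyNA(w)) {
    k <- which(is.na(w))[1]
    stop(sprintf(
      "vorticity stencil touches dry or out-of-grid cells at (x=%.2f, y=%.2f)",
      rep_len(x, length(w))[k], rep_len(y, length(w))[k]))
  }
  w
}

#' Write / read a flow field as portable text
#'
#' Serializes a [flow_field()] to a directory holding a JSON header (grid
#' coordinates, dimensions) and flat CSV tables for `u`, `v`, `bed` and
#' `surface`, so fields round-trip through plain text.
#'
#' @param field A [flow_field()].
#' @param dir Directory to write into (created if missing).
#' @return `write_flow_field()` returns `dir` invisibly;
#'   `read_flow_field()` returns a [flow_field()].
#' @export
write_flow_field <- function(field, dir) {
  stopifnot(inherits(field, "flow_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- list(x = field$x, y = field$y, z = field$z, t = field$t)
  jsonlite::write_json(hdr, file.path(dir, "grid.json"), digits = NA)
  utils::write.csv(data.frame(u = as.vector(field$u), v = as.vector(field$v)),
                   file.path(dir, "velocity.csv"), row.names = FALSE)
  utils::write.csv(data.frame(bed = as.vector(field$bed)),
                   file.path(dir, "bed.csv"), row.names = FALSE)
  utils::write.csv(data.frame(surface = as.vector(field$surface)),
                   file.path(dir, "surface.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_flow_field
#' @export
read_flow_field <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "grid.json"), simplifyVector = TRUE)
  vel <- utils::read.csv(file.path(dir, "velocity.csv"))
  bed <- utils::read.csv(file.path(dir, "bed.csv"))$bed
  surf <- utils::read.csv(file.path(dir, "surface.csv"))$surface
  dm <- c(length(hdr$x), length(hdr$y), length(hdr$z), length(hdr$t))
  flow_field(
    x = hdr$x, y = hdr$y, z = hdr$z, t = hdr$t,
    u = array(vel$u, dm), v = array(vel$v, dm),
    bed = matrix(bed, dm[1], dm[2]),
    surface = array(surf, c(dm[1], dm[2], dm[4]))
  )
}
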