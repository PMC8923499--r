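# Shared fixtures built in code: tiny analytic fields, a triangle array,
# and forward-modeled arrival times.

uniform_field <- function(u = 0.5, v = 0, depth = 4, L = 200, W = 50,
                          duration = 3600) {
  flow_field(
    x = seq(0, L, length.out = 3),
    y = seq(0, W, length.out = 3),
    z = seq(-depth + 0.02, 0, length.out = 5),
    t = c(0, duration),
    u = u, v = v, bed = -depth, surface = 0
  )
}

# u = gamma * y, v = 0  (vorticity -gamma)
shear_field <- function(gamma = 0.05, depth = 4, L = 200, W = 50) {
  y <- seq(0, W, by = 0.5)
  x <- seq(0, L, length.out = 3)
  z <- seq(-depth + 0.02, 0, length.out = 5)
  u <- array(rep(gamma * y, each = length(x)),
             c(length(x), length(y), length(z), 2))
  flow_field(x = x, y = y, z = z, t = c(0, 3600), u = u, v = 0,
             bed = -depth, surface = 0)
}

# solid-body rotation about the domain center (vorticity 2 * omega)
rotation_field <- function(omega = 0.1, depth = 4, L = 100, W = 100) {
  x <- seq(0, L, by = 0.5); y <- seq(0, W, by = 0.5)
  z <- seq(-depth + 0.02, 0, length.out = 5)
  xc <- L / 2; yc <- W / 2
  u2 <- outer(rep(1, length(x)), -omega * (y - yc))
  v2 <- outer(omega * (x - xc), rep(1, length(y)))
  dm <- c(length(x), length(y), length(z), 2)
  flow_field(x = x, y = y, z = z, t = c(0, 3600),
             u = array(u2, dm), v = array(v2, dm),
             bed = -depth, surface = 0)
}

triangle_array <- function(r = 100, z = -3) {
  ang <- c(90, 210, 330) * pi / 180
  tibble::tibble(
    id = c("R01", "R02", "R03"),
    x = r * cos(ang), y = r * sin(ang), z = z,
    role = c("reference", "cabled", "autonomous")
  )
}

# corrected arrival times for a ping emitted at (x, y, tag_z) at time T
forward_arrivals <- function(array, x, y, T = 0, tag_z = -1,
                             sound_speed = 1470) {
  d <- sqrt((array$x - x)^2 + (array$y - y)^2 + (array$z - tag_z)^2)
  tibble::tibble(receiver_id = array$id, source_id = "TAG",
                 corrected_time = T + d / sound_speed)
}

# minimal beacon-only scenario helper
beacon_sim <- function(cfg, duration = 3600, drifts = NULL, seed = 3,
                       array_seed = 1) {
  arr <- gen_array(cfg, seed = array_seed)
  sim <- simulate_detections(NULL, arr, cfg, t_span = c(0, duration),
                             drifts = drifts, seed = seed)
  list(array = arr, sim = sim)
}
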