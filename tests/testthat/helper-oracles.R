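# Independent oracles and small builders used across the test files.

default_params <- function(...) model_params(...)

# Brute-force transversal-crossing count: solves the 2x2 line-intersection
# system for every non-adjacent segment pair (independent of the orientation
# predicate used by the package).
oracle_count_intersections <- function(x, y) {
  keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
  x <- x[keep]; y <- y[keep]
  m <- length(x) - 1L
  cnt <- 0L
  if (m < 3L) return(cnt)
  for (i in 1:(m - 2L)) {
    for (j in (i + 2L):m) {
      ux <- x[i + 1] - x[i]; uy <- y[i + 1] - y[i]
      wx <- x[j + 1] - x[j]; wy <- y[j + 1] - y[j]
      den <- ux * wy - uy * wx
      if (den == 0) next
      rx <- x[j] - x[i]; ry <- y[j] - y[i]
      tt <- (rx * wy - ry * wx) / den
      ss <- (rx * uy - ry * ux) / den
      if (tt > 0 && tt < 1 && ss > 0 && ss < 1) cnt <- cnt + 1L
    }
  }
  cnt
}

# Track from explicit coordinates at unit sampling.
make_track <- function(x, y, interval = 1, nest = c(0, 0)) {
  bee_track(seq_along(x) - 1, x, y, sampling_interval = interval,
            nest = nest)
}

make_loop <- function(x, y, interval = 1, nest = c(0, 0)) {
  beeloop:::as_bee_loop(make_track(x, y, interval, nest))
}

# Single-flower field at a given position, built directly.
point_field <- function(xy, diameter = 0.7, extent = 1000) {
  structure(list(positions = matrix(as.numeric(xy), ncol = 2,
                                    dimnames = list(NULL, c("x", "y"))),
                 flower_diameter = diameter, density = NA_real_,
                 extent = extent, nest = c(0, 0),
                 perception_distance = perception_distance(diameter)),
            class = "bee_field")
}

# Reference R-level integration of one loop, consuming the RNG in the same
# order as the compiled engine (heading, switching time, then one standard
# normal per step); returns the (nsteps + 1) x 2 position matrix.
r_reference_path <- function(params, nsteps, nest = c(0, 0)) {
  theta <- runif(1, -pi, pi)
  tau <- rexp(1, params$p_return)
  st <- bee_state(nest, theta, 0, switch_time = tau, clock = 0)
  out <- matrix(NA_real_, nsteps + 1, 2)
  out[1, ] <- nest
  for (i in seq_len(nsteps)) {
    st <- advance_state(st, params, nest, rnorm(1))
    out[i + 1, ] <- st$position
  }
  out
}
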