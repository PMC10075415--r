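#' Timestamped 2-D track
#'
#' Lightweight container for a sampled trajectory: strictly increasing times
#' (s) and planar positions (m), with the nominal sampling interval and the
#' nest location carried along.  Simulated tracks are recorded at the
#' integration step (or thinned); radar-style tracks are sampled about every
#' 3.3 s.
#'
#' @param t numeric vector of times, s, strictly increasing.
#' @param x,y numeric vectors of coordinates, m.
#' @param sampling_interval nominal sampling interval, s.
#' @param nest nest position, 2-vector, m.
#' @param phase optional integer vector (0 = exploration, 1 = return) aligned
#'   with the samples, for simulated tracks.
#' @return An object of class `bee_track`.
#' @export
bee_track <- function(t, x, y, sampling_interval, nest = c(0, 0),
                      phase = NULL) {
  n <- length(t)
  if (length(x) != n || length(y) != n)
    stop("`t`, `x` and `y` must have equal length")
  if (n > 1 && any(diff(t) <= 0))
    stop("track times must be strictly increasing")
  if (!is.null(phase) && length(phase) != n)
    stop("`phase` must align with the samples")
  structure(list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                 sampling_interval = sampling_interval,
                 nest = as.numeric(nest), phase = phase),
            class = "bee_track")
}

as_bee_loop <- function(track, censored = FALSE, switch_time = NA_real_) {
  track$censored <- censored
  track$switch_time <- switch_time
  class(track) <- c("bee_loop", "bee_track")
  track
}

#' @export
print.bee_track <- function(x, ...) {
  cat(sprintf("<%s> %d samples over %.1f s (interval %.3g s)\n",
              class(x)[1], length(x$t), diff(range(x$t)),
              x$sampling_interval))
  if (!is.null(x$censored) && isTRUE(x$censored)) cat("  censored\n")
  invisible(x)
}

#' @export
as.data.frame.bee_track <- function(x, ...) {
  data.frame(t = x$t, x = x$x, y = x$y)
}

#' Number of samples in a track
#' @param track a [bee_track()].
#' @return Integer sample count.
#' @export
n_samples <- function(track) length(track$t)

track_slice <- function(track, idx) {
  out <- track
  out$t <- track$t[idx]
  out$x <- track$x[idx]
  out$y <- track$y[idx]
  if (!is.null(track$phase)) out$phase <- track$phase[idx]
  out
}

dist_to_nest <- function(track, nest = track$nest) {
  sqrt((track$x - nest[1])^2 + (track$y - nest[2])^2)
}

#' Resample a track at a coarser interval
#'
#' Keeps the samples whose times are nearest to multiples of `interval` from
#' the track start (ties resolved to the earlier sample); the first and last
#' samples are always kept.  Used to bring simulated tracks, recorded at the
#' integration step, to the radar's ~3.3 s resolution before computing
#' observables.
#'
#' @param track a [bee_track()].
#' @param interval target sampling interval, s; at least the native interval.
#' @return The thinned `bee_track` (same class and metadata).
#' @export
resample_track <- function(track, interval) {
  if (interval < track$sampling_interval)
    stop("`interval` must be at least the track's native sampling interval")
  n <- n_samples(track)
  if (n <= 2) return(track)
  targets <- seq(track$t[1], track$t[n], by = interval)
  lo <- findInterval(targets, track$t, all.inside = TRUE)
  hi <- pmin(lo + 1L, n)
  idx <- ifelse(track$t[hi] - targets < targets - track$t[lo], hi, lo)
  idx <- sort(unique(c(idx, n)))
  out <- track_slice(track, idx)
  out$sampling_interval <- interval
  out
}

#' Collapse hovering near flowers to single points
#'
#' Radar recordings of bees exploiting a flower show clusters of points around
#' it; each maximal run of consecutive samples lying within `radius` of the
#' same (nearest) flower is replaced by a single sample at the flower's
#' location, timestamped at the first sample of the run.  The default 6 m is
#' the perception distance of a 20 cm flower (about 4 m) plus 2 m of radar
#' noise.
#'
#' @param track a [bee_track()].
#' @param flower_positions numeric matrix with one row per flower (x, y), m.
#' @param radius collapse radius, m.
#' @return The collapsed `bee_track`.
#' @export
collapse_near_flowers <- function(track, flower_positions, radius = 6) {
  stopifnot(radius > 0)
  fp <- matrix(as.numeric(flower_positions), ncol = 2)
  n <- n_samples(track)
  if (n == 0 || nrow(fp) == 0) return(track)
  assign <- integer(n)
  best <- rep(Inf, n)
  for (j in seq_len(nrow(fp))) {
    d2 <- (track$x - fp[j, 1])^2 + (track$y - fp[j, 2])^2
    hit <- d2 <= radius^2 & d2 < best
    assign[hit] <- j
    best[hit] <- d2[hit]
  }
  if (all(assign == 0)) return(track)
  r <- rle(assign)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  t_out <- x_out <- y_out <- numeric(0)
  for (k in seq_along(r$values)) {
    if (r$values[k] == 0) {
      idx <- starts[k]:ends[k]
      t_out <- c(t_out, track$t[idx])
      x_out <- c(x_out, track$x[idx])
      y_out <- c(y_out, track$y[idx])
    } else {
      t_out <- c(t_out, track$t[starts[k]])
      x_out <- c(x_out, fp[r$values[k], 1])
      y_out <- c(y_out, fp[r$values[k], 2])
    }
  }
  bee_track(t_out, x_out, y_out,
            sampling_interval = track$sampling_interval, nest = track$nest)
}

#' Segment a track into nest-to-nest loops
#'
#' A loop spans from the last sample inside the nest disc before an excursion
#' to the first sample back inside it, so the boundary samples are included
#' and lengths are not truncated.  An excursion still open at the end of the
#' track yields a loop flagged `censored`; samples that never leave the disc
#' produce no loop.  The 13 m default excludes short learning flights around
#' the nest box in experimental data and is used identically on simulations.
#'
#' @param track a [bee_track()] with at least 3 samples.
#' @param nest nest position, 2-vector, m.
#' @param nest_radius loop-delimiting radius, m.
#' @return A list of `bee_loop` objects.
#' @export
extract_loops <- function(track, nest = track$nest, nest_radius = 13) {
  if (n_samples(track) < 3) stop("track must have at least 3 samples")
  d <- dist_to_nest(track, nest)
  outside <- d > nest_radius
  r <- rle(outside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  loops <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i0 <- max(starts[k] - 1L, 1L)
    censored <- ends[k] == n_samples(track)
    i1 <- if (censored) ends[k] else ends[k] + 1L
    loops[[length(loops) + 1L]] <-
      as_bee_loop(track_slice(track, i0:i1), censored = censored)
  }
  loops
}
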