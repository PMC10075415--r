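#' Total path length of a loop
#'
#' @param loop a `bee_loop` (or any [bee_track()]) with at least 2 samples.
#' @return Sum of consecutive-sample Euclidean distances, m.
#' @export
loop_length <- function(loop) {
  if (n_samples(loop) < 2) stop("loop must have at least 2 samples")
  sum(sqrt(diff(loop$x)^2 + diff(loop$y)^2))
}

#' Maximum distance from the nest within a loop
#'
#' @inheritParams loop_length
#' @param nest nest position, 2-vector, m.
#' @return Loop extension, m.
#' @export
loop_extension <- function(loop, nest = loop$nest) {
  max(dist_to_nest(loop, nest))
}

#' Count transversal self-intersections of a loop
#'
#' Counts crossings between non-adjacent segments of the sampled polyline;
#' shared endpoints of consecutive segments are not crossings, touching or
#' collinear overlaps are not counted, and each crossing is counted once.
#'
#' @inheritParams loop_length
#' @return Integer crossing count.
#' @export
count_self_intersections <- function(loop) {
  if (n_samples(loop) < 4) stop("loop must have at least 4 samples")
  x <- loop$x; y <- loop$y
  keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
  x <- x[keep]; y <- y[keep]
  m <- length(x) - 1L
  if (m < 3L) return(0L)
  # all segment pairs (i, j) with j >= i + 2
  i <- rep.int(seq_len(m - 2L), (m - 2L):1L)
  j <- sequence((m - 2L):1L, from = seq_len(m - 2L) + 2L)
  ax <- x[i]; ay <- y[i]; bx <- x[i + 1L]; by <- y[i + 1L]
  cx <- x[j]; cy <- y[j]; dx <- x[j + 1L]; dy <- y[j + 1L]
  d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  sum(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Count re-departures within a loop
#'
#' A re-departure is three consecutive sampled positions such that the second
#' is closer to the nest than the first but the third is again further than
#' the second: the bee seemed to head home, then turned back out.  The count
#' is direction-dependent (reversing the loop counts re-approaches instead).
#'
#' @inheritParams loop_extension
#' @return Integer re-departure count.
#' @export
count_redepartures <- function(loop, nest = loop$nest) {
  if (n_samples(loop) < 3) stop("loop must have at least 3 samples")
  d <- dist_to_nest(loop, nest)
  n <- length(d)
  sum(d[2:(n - 1)] < d[1:(n - 2)] & d[3:n] > d[2:(n - 1)])
}

#' The four calibration observables of one loop
#'
#' Loop length and extension (continuous, m), plus self-intersections and
#' re-departures expressed as counts per 100 m travelled and binned to the
#' nearest integer, which makes them discrete observables with a well-defined
#' probability mass function.
#'
#' @inheritParams loop_extension
#' @return A one-row data frame with columns `loop_length`, `loop_extension`,
#'   `intersections_per_100m`, `redepartures_per_100m`.
#' @export
loop_observables <- function(loop, nest = loop$nest) {
  len <- loop_length(loop)
  if (len <= 0) stop("zero-length loop")
  n <- n_samples(loop)
  n_int <- if (n >= 4) count_self_intersections(loop) else 0L
  n_red <- if (n >= 3) count_redepartures(loop, nest) else 0L
  data.frame(
    loop_length = len,
    loop_extension = loop_extension(loop, nest),
    intersections_per_100m = as.integer(round(n_int / (len / 100))),
    redepartures_per_100m = as.integer(round(n_red / (len / 100))))
}

#' Observable samples pooled over a set of loops
#'
#' Censored loops are excluded.  Simulated loops recorded at the integration
#' step are resampled to `interval` first (default 3.3 s, the radar's
#' resolution), because the discrete observables depend on the sampling rate
#' and the calibration compares simulated distributions with radar-derived
#' ones; pass `interval = NULL` to compute at native resolution.
#'
#' @param loops list of `bee_loop` objects.
#' @param nest nest position, 2-vector, m.
#' @param interval resampling interval, s, or `NULL`.
#' @return A list with numeric vectors `loop_length`, `loop_extension` and
#'   integer vectors `intersections_per_100m`, `redepartures_per_100m`, plus
#'   `n_censored`.
#' @export
observable_samples <- function(loops, nest = c(0, 0), interval = 3.3) {
  censored <- vapply(loops, function(l) isTRUE(l$censored), logical(1))
  kept <- loops[!censored]
  rows <- lapply(kept, function(l) {
    if (!is.null(interval) && interval > l$sampling_interval)
      l <- resample_track(l, interval)
    loop_observables(l, nest)
  })
  tab <- do.call(rbind, rows)
  list(loop_length = tab$loop_length,
       loop_extension = tab$loop_extension,
       intersections_per_100m = tab$intersections_per_100m,
       redepartures_per_100m = tab$redepartures_per_100m,
       n_censored = sum(censored))
}

#' Per-loop observable table
#'
#' @inheritParams observable_samples
#' @return Data frame with one row per loop: `loop_id`, `n_points`,
#'   `length_m`, `extension_m`, `intersections_per100m`,
#'   `redepartures_per100m`, `censored`.
#' @export
loops_table <- function(loops, nest = c(0, 0), interval = 3.3) {
  rows <- lapply(seq_along(loops), function(k) {
    l <- loops[[k]]
    if (!is.null(interval) && interval > l$sampling_interval)
      l <- resample_track(l, interval)
    ob <- loop_observables(l, nest)
    data.frame(loop_id = k, n_points = n_samples(l),
               length_m = ob$loop_length, extension_m = ob$loop_extension,
               intersections_per100m = ob$intersections_per_100m,
               redepartures_per100m = ob$redepartures_per_100m,
               censored = isTRUE(l$censored))
  })
  do.call(rbind, rows)
}
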