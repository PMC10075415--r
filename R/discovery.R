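#' Trip-termination policy for flower discovery
#'
#' `"none"`: the bee records every flower whose perception zone it enters but
#' never stops (the no-masking baseline).  `"masking"`: the trip truncates at
#' the `flowers_per_trip`-th discovery (the paper's basic masking model is
#' `flowers_per_trip = 1`).  `"depletion"`: flowers already depleted by
#' earlier trips do not stop the bee; the trip truncates at the first fresh
#' discovery or after `max_depleted_visits` distinct depleted-flower
#' encounters.
#'
#' @param mode one of `"none"`, `"masking"`, `"depletion"`.
#' @param flowers_per_trip discoveries that end a masking trip (F >= 1).
#' @param max_depleted_visits depleted-flower encounter budget (may be `Inf`).
#' @return An object of class `bee_policy`.
#' @export
discovery_policy <- function(mode = c("masking", "none", "depletion"),
                             flowers_per_trip = 1,
                             max_depleted_visits = Inf) {
  mode <- match.arg(mode)
  stopifnot(flowers_per_trip >= 1, max_depleted_visits >= 1)
  structure(list(mode = mode,
                 flowers_per_trip = as.integer(flowers_per_trip),
                 max_depleted_visits = max_depleted_visits,
                 code = c(none = 0L, masking = 1L, depletion = 2L)[[mode]]),
            class = "bee_policy")
}

#' Run one foraging trip through a flower field
#'
#' Simulates a multi-loop trip and tests, at every integration step, whether
#' the bee is within the field's perception distance of a flower centre.
#' Each flower is discovered at most once per trip; the policy decides whether
#' a discovery truncates the trip.  The step length (speed * dt, about 5 cm at
#' the defaults) is far below the metre-scale perception distances, so
#' discrete-point detection does not miss zone crossings.
#'
#' @param params a [model_params()].
#' @param field a [generate_field()] result.
#' @param policy a [discovery_policy()].
#' @param duration trip duration, s.
#' @param depleted logical vector flagging depleted flowers (depletion mode).
#' @param record if `TRUE`, keep the full track at `record_interval`.
#' @param record_interval recording resolution when `record = TRUE`, s.
#' @return An object of class `bee_trip`: `discovered` (flower ids in
#'   encounter order), `discovery_times` (s), `end_time` (s), `truncated`
#'   (ended by the policy rather than the clock), `n_depleted_encounters`,
#'   and `track` (a [bee_track()] or `NULL`).
#' @export
run_trip_with_discovery <- function(params, field,
                                    policy = discovery_policy("masking"),
                                    duration = 900,
                                    depleted = NULL, record = FALSE,
                                    record_interval = params$dt) {
  nf <- nrow(field$positions)
  if (is.null(depleted)) depleted <- rep(FALSE, nf)
  stopifnot(length(depleted) == nf)
  every <- if (record) record_steps(record_interval, params$dt) else
    .Machine$integer.max
  fdep <- if (is.finite(policy$max_depleted_visits))
    policy$max_depleted_visits else Inf
  res <- cpp_ptw_simulate(params$gamma, params$sigma, params$eta_star,
                          params$p_return, params$speed, params$dt,
                          params$nest_radius, params$max_loop_duration,
                          field$nest, duration, FALSE, every,
                          field$positions, field$perception_distance,
                          policy$code, policy$flowers_per_trip, fdep,
                          depleted)
  track <- NULL
  if (record) {
    track <- bee_track(res$track[, 1], res$track[, 2], res$track[, 3],
                       sampling_interval = record_interval,
                       nest = field$nest, phase = res$phase)
    track$loop_entries <- res$loop_entries
  }
  structure(list(discovered = res$discovered,
                 discovery_times = res$discovery_times,
                 end_time = res$end_time, truncated = res$truncated,
                 n_depleted_encounters = res$n_depleted_encounters,
                 track = track),
            class = "bee_trip")
}

#' Per-trip flower discovery probability by distance to the nest
#'
#' For each random environment, runs `n_trips` independent trips and records,
#' for every flower, the fraction of trips that discovered it; flowers are
#' binned by distance to the nest, per-flower probabilities are averaged
#' within bins, and bin means are averaged over environments (bins with no
#' flowers in an environment are ignored; bins empty in every environment get
#' `NA`).  When `seed` is given, fields and trips use seeds derived from it,
#' so profiles for different policies at the same `seed` share trip-by-trip
#' trajectories (a masking trip is then an exact truncation of its no-masking
#' counterpart).
#'
#' @param params a [model_params()].
#' @param density flower density, flowers/m^2.
#' @param diameter flower diameter, m.
#' @param policy a [discovery_policy()].
#' @param n_trips trips per environment.
#' @param n_environments number of random fields.
#' @param bin_width distance-bin width, m.
#' @param max_distance outer edge of the last bin, m.
#' @param extent field half-width, m.
#' @param trip_duration trip duration, s.
#' @param seed optional integer seed for paired-policy comparisons.
#' @return An object of class `bee_discovery_profile`: data frame with
#'   `bin_lo`, `bin_hi`, `p_discovery`, `n_flowers` plus metadata attributes.
#' @export
discovery_probability_profile <- function(params, density, diameter,
                                          policy = discovery_policy("masking"),
                                          n_trips = 200,
                                          n_environments = 20,
                                          bin_width = 10, max_distance = 500,
                                          extent = 1000, trip_duration = 900,
                                          seed = NULL) {
  edges <- seq(0, max_distance, by = bin_width)
  nb <- length(edges) - 1L
  bin_sum <- numeric(nb)
  bin_envs <- integer(nb)
  bin_nfl <- integer(nb)
  for (e in seq_len(n_environments)) {
    if (!is.null(seed)) set.seed(mix_seed(seed, e, 0L))
    field <- generate_field(density, diameter, extent)
    nf <- nrow(field$positions)
    if (nf == 0) next
    hits <- integer(nf)
    for (i in seq_len(n_trips)) {
      if (!is.null(seed)) set.seed(mix_seed(seed, e, i))
      out <- run_trip_with_discovery(params, field, policy,
                                     duration = trip_duration)
      hits[out$discovered] <- hits[out$discovered] + 1L
    }
    fd <- sqrt(rowSums(sweep(field$positions, 2, field$nest)^2))
    bin <- findInterval(fd, edges, rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= nb
    p <- hits / n_trips
    for (b in unique(bin[ok])) {
      sel <- ok & bin == b
      bin_sum[b] <- bin_sum[b] + mean(p[sel])
      bin_envs[b] <- bin_envs[b] + 1L
      bin_nfl[b] <- bin_nfl[b] + sum(sel)
    }
  }
  prof <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                     p_discovery = ifelse(bin_envs > 0, bin_sum /
                                            pmax(bin_envs, 1L), NA_real_),
                     n_flowers = bin_nfl)
  structure(prof, class = c("bee_discovery_profile", "data.frame"),
            density = density, diameter = diameter, policy = policy$mode,
            n_trips = n_trips, n_environments = n_environments)
}

#' Discovery radius of a profile
#'
#' The outer edge of the farthest distance bin whose discovery probability
#' remains at or above `threshold`, with every nearer (non-empty) bin also
#' above it; 0 if the nearest non-empty bin is already below.  Bins that held
#' no flowers (`NA` probability) are skipped.
#'
#' @param profile a [discovery_probability_profile()] result.
#' @param threshold per-trip probability threshold.
#' @return Radius, m.
#' @export
discovery_radius <- function(profile, threshold = 1e-2) {
  if (nrow(profile) == 0) return(0)
  radius <- 0
  for (k in seq_len(nrow(profile))) {
    p <- profile$p_discovery[k]
    if (is.na(p)) next
    if (p >= threshold) radius <- profile$bin_hi[k] else break
  }
  radius
}

#' Distinct flowers discovered by a colony
#'
#' For each replicate, fixes one random environment and runs `n_trips`
#' sequential trips under the policy; in depletion mode every flower
#' discovered on a trip is marked depleted for the subsequent trips of the
#' same replicate.  Reports the number of distinct flowers discovered at
#' least once, averaged over replicates.
#'
#' @inheritParams discovery_probability_profile
#' @param n_trips sequential trips per replicate (one colony's exploration).
#' @param n_replicates independent environments/colonies.
#' @return A list with `mean_distinct`, `sd`, and the per-replicate `counts`.
#' @export
colony_distinct_flowers <- function(params, density, diameter,
                                    policy = discovery_policy("masking"),
                                    n_trips = 100, n_replicates = 80,
                                    trip_duration = 900, extent = 1000,
                                    seed = NULL) {
  counts <- integer(n_replicates)
  for (r in seq_len(n_replicates)) {
    if (!is.null(seed)) set.seed(mix_seed(seed, r, 0L))
    field <- generate_field(density, diameter, extent)
    nf <- nrow(field$positions)
    depleted <- rep(FALSE, nf)
    found <- rep(FALSE, nf)
    for (i in seq_len(n_trips)) {
      if (!is.null(seed)) set.seed(mix_seed(seed, r, i))
      out <- run_trip_with_discovery(params, field, policy,
                                     duration = trip_duration,
                                     depleted = depleted)
      found[out$discovered] <- TRUE
      if (policy$mode == "depletion") depleted[out$discovered] <- TRUE
    }
    counts[r] <- sum(found)
  }
  list(mean_distinct = mean(counts), sd = sd(counts), counts = counts)
}

#' Mean squared distance to the nest of the loop-chained process
#'
#' Estimates the long-run mean squared displacement (the variance scale of
#' the stationary spatial distribution around the nest) by pooling squared
#' distances sampled at `sample_interval` over `n_loops` independent loops.
#' Positions from censored loops contribute up to the censoring time, so
#' weakly attracting, nearly diffusive parameter sets are not biased low.
#'
#' @param params a [model_params()].
#' @param n_loops number of loops.
#' @param sample_interval spacing of the pooled samples, s.
#' @return MSD in m^2, with attributes `n_samples` and `n_censored`.
#' @export
estimate_msd <- function(params, n_loops = 1e4, sample_interval = 1) {
  stopifnot(n_loops >= 1)
  k <- record_steps(sample_interval, params$dt)
  res <- cpp_msd(params$gamma, params$sigma, params$eta_star,
                 params$p_return, params$speed, params$dt,
                 params$nest_radius, params$max_loop_duration,
                 as.integer(n_loops), k)
  structure(res$msd, n_samples = res$n_samples,
            n_censored = res$n_censored)
}

mix_seed <- function(seed, a = 0L, b = 0L) {
  as.integer((as.numeric(seed) * 48271 + a * 104729 + b * 7919) %%
               2147483587)
}
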