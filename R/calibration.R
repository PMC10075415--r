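#' Area between two empirical cumulative distribution functions
#'
#' Exact piecewise-constant integral of |F_a - F_b| over the union support
#' (no binning); the distance used for the two continuous loop observables.
#'
#' @param sample_a,sample_b non-empty numeric samples.
#' @return Non-negative area.
#' @export
ecdf_area_distance <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("samples must be non-empty")
  xs <- sort(unique(c(sample_a, sample_b)))
  if (length(xs) == 1) return(0)
  fa <- ecdf(sample_a)(xs)
  fb <- ecdf(sample_b)(xs)
  sum(abs(fa - fb)[-length(xs)] * diff(xs))
}

#' L1 distance between two empirical probability mass functions
#'
#' Sum of absolute differences of relative frequencies over the union of
#' observed values; the distance used for the two discrete loop observables.
#' Bounded by 2, attained for disjoint supports.
#'
#' @param counts_a,counts_b non-empty integer-valued samples.
#' @return Non-negative distance in [0, 2].
#' @export
pmf_l1_distance <- function(counts_a, counts_b) {
  if (length(counts_a) == 0 || length(counts_b) == 0)
    stop("samples must be non-empty")
  vals <- sort(unique(c(counts_a, counts_b)))
  pa <- tabulate(match(counts_a, vals), length(vals)) / length(counts_a)
  pb <- tabulate(match(counts_b, vals), length(vals)) / length(counts_b)
  sum(abs(pa - pb))
}

#' Quantile-normalize distances across parameter combinations
#'
#' Translates each combination's distance for one observable into its quantile
#' within the distribution of that observable's distances over all
#' combinations (rank/N, mid-ranks for ties), putting heterogeneous
#' observables on a common [0, 1] scale before averaging.  Order-preserving,
#' so the final ranking depends only on within-observable orderings.
#'
#' @param distances numeric vector, one distance per combination (length >= 2).
#' @return Scores in (0, 1], same length.
#' @export
quantile_scores <- function(distances) {
  if (length(distances) < 2) stop("need at least 2 combinations")
  rank(distances, ties.method = "average") / length(distances)
}

#' Parameter grid for the calibration search
#'
#' Combinations are enumerated in lexicographic order of (gamma, omega_var,
#' alpha, eta_star), which also fixes the deterministic tie-break of
#' [fit_grid()].
#'
#' @param gamma_values,omega_values,alpha_values,eta_values sorted numeric
#'   vectors of candidate values.
#' @return An object of class `bee_grid` wrapping the combination data frame.
#' @export
parameter_grid <- function(gamma_values, omega_values, alpha_values,
                           eta_values) {
  g <- expand.grid(eta_star = sort(eta_values), alpha = sort(alpha_values),
                   omega_var = sort(omega_values),
                   gamma = sort(gamma_values),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("gamma", "omega_var", "alpha", "eta_star")]
  rownames(g) <- NULL
  structure(list(combinations = g), class = "bee_grid")
}

#' The default calibration grid (6160 combinations)
#'
#' 11 values of gamma, 10 of the stationary angular-speed variance, 7 of the
#' mean exploration duration and 8 of the homing strength.
#'
#' @return A `bee_grid` with 6160 combinations.
#' @export
default_parameter_grid <- function() {
  parameter_grid(
    gamma_values = seq(0.5, 1.5, by = 0.1),
    omega_values = c(0.01, 0.03, 0.05, 0.06, 0.07, 0.08, 0.09, 0.1,
                     0.125, 0.15),
    alpha_values = c(10, 20, 25, 30, 35, 40, 50),
    eta_values = seq(0.05, 0.4, by = 0.05))
}

#' @export
print.bee_grid <- function(x, ...) {
  cat(sprintf("<bee_grid> %d parameter combinations\n",
              nrow(x$combinations)))
  invisible(x)
}

reference_samples <- function(reference, nest, interval) {
  if (is.list(reference) && !is.null(reference$loop_length)) {
    reference
  } else if (is.data.frame(reference)) {
    cols <- c(loop_length = "length_m", loop_extension = "extension_m",
              intersections_per_100m = "intersections_per100m",
              redepartures_per_100m = "redepartures_per100m")
    if (!all(cols %in% names(reference)))
      stop("reference table must have columns ", paste(cols, collapse = ", "))
    ref <- if ("censored" %in% names(reference))
      reference[!reference$censored, , drop = FALSE] else reference
    list(loop_length = ref$length_m, loop_extension = ref$extension_m,
         intersections_per_100m = ref$intersections_per100m,
         redepartures_per_100m = ref$redepartures_per100m)
  } else if (is.list(reference) && length(reference) > 0 &&
             inherits(reference[[1]], "bee_loop")) {
    observable_samples(reference, nest = nest, interval = interval)
  } else {
    stop("`reference` must be a list of loops, an observable-sample list, ",
         "or a loop table")
  }
}

comb_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 10007 + k * 7919) %% 2147483587)
}

#' Grid-search calibration against reference observable distributions
#'
#' For every parameter combination, simulates `n_loops` loops, computes the
#' four observable distributions, and measures their discrepancy from the
#' reference: ECDF-area distance for the two continuous observables, L1
#' distance between probability mass functions for the two discrete ones.
#' Each observable's distances are quantile-normalized across combinations
#' and averaged; the returned best combination minimizes the mean quantile
#' score (ties broken by grid order, lexicographic in the parameters).
#' Deterministic given `seed`, the grid and `n_loops`: each combination uses
#' its own seed derived from `seed` and the combination index.
#'
#' @param reference a list of `bee_loop`s, a list of observable samples (as
#'   from [observable_samples()]), or a loop table (as from [loops_table()]).
#' @param grid a [parameter_grid()]; default the full 6160-combination grid.
#' @param n_loops simulated loops per combination.
#' @param seed integer seed.
#' @param base_params a [model_params()] supplying speed, dt, nest radius and
#'   censoring cap; the four behavioural parameters come from the grid.
#' @param obs_interval resampling interval for simulated observables, s.
#' @param nest nest position, 2-vector, m.
#' @param progress print progress every 200 combinations.
#' @return An object of class `bee_fit`: list with `table` (one row per
#'   combination: parameters, four distances, four quantile scores,
#'   `mean_score`, `n_censored`), `best`, `best_index`, `seed`, `n_loops`.
#'   Combinations whose loops were all censored get infinite distances.
#' @export
fit_grid <- function(reference, grid = default_parameter_grid(),
                     n_loops = 1000, seed = 1L,
                     base_params = model_params(), obs_interval = 3.3,
                     nest = c(0, 0), progress = FALSE) {
  ref <- reference_samples(reference, nest, obs_interval)
  if (length(ref$loop_length) == 0) stop("reference loops are all censored")
  combs <- grid$combinations
  nc <- nrow(combs)
  dist <- matrix(NA_real_, nc, 4,
                 dimnames = list(NULL, c("d_length", "d_extension",
                                         "d_intersections",
                                         "d_redepartures")))
  n_cens <- integer(nc)
  for (k in seq_len(nc)) {
    set.seed(comb_seed(seed, k))
    p <- model_params(gamma = combs$gamma[k],
                      omega_var = combs$omega_var[k],
                      alpha = combs$alpha[k], eta_star = combs$eta_star[k],
                      speed = base_params$speed, dt = base_params$dt,
                      nest_radius = base_params$nest_radius,
                      max_loop_duration = base_params$max_loop_duration)
    rec <- if (abs(round(obs_interval / p$dt) * p$dt - obs_interval) < 1e-9)
      obs_interval else p$dt
    loops <- replicate(n_loops, simulate_loop(p, nest, rec),
                       simplify = FALSE)
    sim <- observable_samples(loops, nest = nest, interval = obs_interval)
    n_cens[k] <- sim$n_censored
    if (length(sim$loop_length) == 0) {
      dist[k, ] <- Inf
    } else {
      dist[k, ] <- c(
        ecdf_area_distance(ref$loop_length, sim$loop_length),
        ecdf_area_distance(ref$loop_extension, sim$loop_extension),
        pmf_l1_distance(ref$intersections_per_100m,
                        sim$intersections_per_100m),
        pmf_l1_distance(ref$redepartures_per_100m,
                        sim$redepartures_per_100m))
    }
    if (progress && k %% 200 == 0)
      message(sprintf("fit_grid: %d/%d combinations", k, nc))
  }
  if (nc >= 2) {
    scores <- apply(dist, 2, quantile_scores)
    if (is.null(dim(scores))) scores <- matrix(scores, nrow = nc)
  } else {
    scores <- matrix(0.5, 1, 4)
  }
  colnames(scores) <- c("q_length", "q_extension", "q_intersections",
                        "q_redepartures")
  mean_score <- rowMeans(scores)
  best_index <- which.min(mean_score)
  table <- cbind(combs, as.data.frame(dist), as.data.frame(scores),
                 mean_score = mean_score, n_censored = n_cens)
  structure(list(table = table, best = combs[best_index, , drop = FALSE],
                 best_index = best_index, seed = seed, n_loops = n_loops),
            class = "bee_fit")
}

#' @export
print.bee_fit <- function(x, ...) {
  cat(sprintf("<bee_fit> %d combinations, %d loops each (seed %s)\n",
              nrow(x$table), x$n_loops, format(x$seed)))
  b <- x$best
  cat(sprintf("  best: gamma %.3g, Omega %.3g, alpha %.3g, eta* %.3g (mean score %.4f)\n",
              b$gamma, b$omega_var, b$alpha, b$eta_star,
              x$table$mean_score[x$best_index]))
  invisible(x)
}
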