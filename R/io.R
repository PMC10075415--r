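#' Write / read a track as CSV
#'
#' Plain `t,x,y` CSV (seconds, metres, nest at the origin by convention).
#'
#' @param track a [bee_track()].
#' @param path file path.
#' @param sampling_interval interval to assume when reading; inferred from
#'   the median time step if `NULL`.
#' @param nest nest position to attach when reading.
#' @return `write_track` returns `path` invisibly; `read_track` a
#'   `bee_track`.
#' @export
write_track <- function(track, path) {
  write.csv(as.data.frame(track), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path, sampling_interval = NULL, nest = c(0, 0)) {
  df <- read.csv(path)
  if (!all(c("t", "x", "y") %in% names(df)))
    stop("track CSV must have columns t,x,y")
  if (is.null(sampling_interval))
    sampling_interval <- stats::median(diff(df$t))
  bee_track(df$t, df$x, df$y, sampling_interval = sampling_interval,
            nest = nest)
}

#' Write a per-loop observable table as CSV
#'
#' @param loops list of `bee_loop`s.
#' @param path file path.
#' @param nest nest position, 2-vector, m.
#' @param interval observable resampling interval, s (see
#'   [observable_samples()]).
#' @return `path`, invisibly.
#' @export
write_loop_table <- function(loops, path, nest = c(0, 0), interval = 3.3) {
  write.csv(loops_table(loops, nest, interval), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

run_config_keys <- c("gamma", "sigma", "omega_var", "p_return", "alpha",
                     "eta_star", "speed", "dt", "nest_radius",
                     "max_loop_duration", "seed", "density",
                     "flower_diameter", "extent", "angular_threshold_deg",
                     "n_loops", "n_trips", "n_environments",
                     "trip_duration", "out")

#' Read / write a flat run configuration (YAML)
#'
#' Flat keys only; unknown keys are rejected so typos fail loudly.  Either
#' member of the `sigma`/`omega_var` and `alpha`/`p_return` pairs may be
#' given.
#'
#' @param path file path.
#' @param config named list of configuration values.
#' @return `read_run_config` returns the named list; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), run_config_keys)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  yaml::write_yaml(config, path)
  invisible(path)
}

params_from_config <- function(cfg) {
  take <- function(k) if (!is.null(cfg[[k]])) cfg[[k]] else NULL
  args <- list(sigma = take("sigma"), omega_var = take("omega_var"),
               p_return = take("p_return"), alpha = take("alpha"))
  for (k in c("gamma", "eta_star", "speed", "dt", "nest_radius",
              "max_loop_duration"))
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  do.call(model_params, args)
}
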