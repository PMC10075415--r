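#' Visual perception distance of an object
#'
#' Bumblebees resolve an object once it subtends about 3 degrees on the
#' retina; the perception distance is where an object of the given diameter
#' subtends exactly that angle, `d = diameter / (2 * tan(threshold / 2))`.
#' Linear in diameter; a 20 cm flower is perceived at about 3.8 m (4 m to the
#' nearest metre) and a 37 cm nest box at about 7 m.
#'
#' @param object_diameter object diameter, m.
#' @param angular_threshold angular detection threshold, rad (default 3
#'   degrees).
#' @return Perception distance, m.
#' @export
perception_distance <- function(object_diameter,
                                angular_threshold = 3 * pi / 180) {
  if (any(object_diameter < 0)) stop("`object_diameter` must be >= 0")
  if (angular_threshold <= 0 || angular_threshold >= pi)
    stop("`angular_threshold` must be in (0, pi)")
  object_diameter / (2 * tan(angular_threshold / 2))
}

#' Generate a random uniform flower field
#'
#' Flowers (feeding locations) of a common diameter are placed independently
#' and uniformly over a square of half-width `extent` centred on the nest.
#' The count is fixed at `round(density * area)` rather than Poisson, so a
#' given density always yields the same number of flowers.
#'
#' @param density mean flower density, flowers/m^2.
#' @param diameter flower diameter, m.
#' @param extent half-width of the square field, m.
#' @param nest field centre (nest position), 2-vector, m.
#' @param angular_threshold visual detection threshold, rad.
#' @return An object of class `bee_field`: positions (n x 2 matrix, m),
#'   `flower_diameter`, `density`, `extent`, `nest` and the derived
#'   `perception_distance`.
#' @export
generate_field <- function(density, diameter, extent = 1000,
                           nest = c(0, 0),
                           angular_threshold = 3 * pi / 180) {
  stopifnot(density >= 0, diameter >= 0, extent > 0)
  n <- round(density * (2 * extent)^2)
  pos <- cbind(x = runif(n, -extent, extent) + nest[1],
               y = runif(n, -extent, extent) + nest[2])
  structure(list(positions = pos, flower_diameter = diameter,
                 density = density, extent = extent, nest = as.numeric(nest),
                 perception_distance =
                   perception_distance(diameter, angular_threshold)),
            class = "bee_field")
}

#' @export
print.bee_field <- function(x, ...) {
  cat(sprintf(
    "<bee_field> %d flowers (density %.3g /m^2, diameter %.2g m) over +/-%g m\n",
    nrow(x$positions), x$density, x$flower_diameter, x$extent))
  cat(sprintf("  perception distance %.2f m\n", x$perception_distance))
  invisible(x)
}

#' Write / read a flower field as CSV
#'
#' Columns `flower_id,x,y,diameter`.
#'
#' @param field a `bee_field`.
#' @param path file path.
#' @return `write_field` returns `path` invisibly; `read_field` a `bee_field`
#'   (density and extent reconstructed from the positions).
#' @export
write_field <- function(field, path) {
  df <- data.frame(flower_id = seq_len(nrow(field$positions)),
                   x = field$positions[, 1], y = field$positions[, 2],
                   diameter = field$flower_diameter)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  df <- read.csv(path)
  extent <- max(abs(c(df$x, df$y)), 1)
  structure(list(positions = cbind(x = df$x, y = df$y),
                 flower_diameter = df$diameter[1],
                 density = nrow(df) / (2 * extent)^2, extent = extent,
                 nest = c(0, 0),
                 perception_distance = perception_distance(df$diameter[1])),
            class = "bee_field")
}
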