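#' Specify a synthetic tax-value exposure surface
#'
#' An `surface_spec` describes the bounded "city" used by the synthetic-data
#' generator: a 30 m pixel grid tiled by rectangular tax parcels, with a
#' street grid of road pixels that carry no taxable value of their own.
#' Pixel size is fixed at 30 m to match the resolution at which parcel
#' tax values are mapped.
#'
#' @param grid_shape integer vector `c(rows, cols)` of pixel counts.
#' @param n_parcels number of rectangular parcels tiling the non-road area.
#' @param category_set character vector of property categories (>= 2).
#' @param category_probs sampling probabilities per category (sums to 1).
#' @param value_meanlog,value_sdlog per-category log-normal parameters for
#'   taxable value (natural-log scale), named by category.
#' @param road_fraction approximate proportion of pixels that are road.
#' @param poverty_gradient trend coefficient on log value per unit of
#'   relative easting (column position scaled to \[0, 1\]); positive values
#'   make the east side richer.
#' @param seed RNG seed for surface generation.
#'
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(grid_shape = c(60L, 60L),
                         n_parcels = 120L,
                         category_set = c("residential", "commercial",
                                          "industrial", "exempt"),
                         category_probs = NULL,
                         value_meanlog = NULL,
                         value_sdlog = NULL,
                         road_fraction = 0.15,
                         poverty_gradient = 1.0,
                         seed = 1L) {
  abort_if(length(grid_shape) != 2L || any(grid_shape < 1),
           "grid_shape must be two positive pixel counts")
  abort_if(n_parcels < 1, "n_parcels must be positive")
  abort_if(length(category_set) < 2, "need at least two property categories")
  abort_if(road_fraction < 0 || road_fraction >= 1,
           "road_fraction must be in [0, 1)")
  if (is.null(category_probs)) {
    category_probs <- c(0.6, 0.15, 0.1, 0.15)[seq_along(category_set)]
    category_probs <- category_probs / sum(category_probs)
  }
  abort_if(length(category_probs) != length(category_set) ||
             any(category_probs < 0) || sum(category_probs) <= 0,
           "category_probs must be valid sampling probabilities")
  category_probs <- category_probs / sum(category_probs)
  if (is.null(value_meanlog)) {
    value_meanlog <- c(log(150000), log(400000), log(250000), log(20000)
    )[seq_along(category_set)]
  }
  if (is.null(value_sdlog)) {
    value_sdlog <- c(0.5, 0.8, 0.7, 1.0)[seq_along(category_set)]
  }
  structure(list(
    pixel_size = 30,
    grid_shape = as.integer(grid_shape),
    n_parcels = as.integer(n_parcels),
    category_set = category_set,
    category_probs = category_probs,
    value_meanlog = stats::setNames(value_meanlog, category_set),
    value_sdlog = stats::setNames(value_sdlog, category_set),
    road_fraction = road_fraction,
    poverty_gradient = poverty_gradient,
    seed = as.integer(seed)
  ), class = "surface_spec")
}

# Recursive guillotine partition of the pixel grid into n rectangles.
# Rectangles are half-open in pixel units: rows [r0, r1), cols [c0, c1).
partition_rectangles <- function(rows, cols, n) {
  rects <- list(c(0L, rows, 0L, cols))
  while (length(rects) < n) {
    areas <- vapply(rects, function(r) (r[2] - r[1]) * (r[4] - r[3]), 0)
    splittable <- which(vapply(
      rects, function(r) (r[2] - r[1]) > 1 || (r[4] - r[3]) > 1, TRUE))
    if (!length(splittable)) break
    i <- splittable[which.max(areas[splittable])]
    r <- rects[[i]]
    h <- r[2] - r[1]; w <- r[4] - r[3]
    if (h >= w) {
      cut <- r[1] + sample.int(h - 1L, 1L)
      new <- list(c(r[1], cut, r[3], r[4]), c(cut, r[2], r[3], r[4]))
    } else {
      cut <- r[3] + sample.int(w - 1L, 1L)
      new <- list(c(r[1], r[2], r[3], cut), c(r[1], r[2], cut, r[4]))
    }
    rects <- c(rects[-i], new)
  }
  rects
}

#' Generate a synthetic exposure surface
#'
#' Draws a rectangular parcel partition of the grid, samples a property
#' category and log-normal taxable value per parcel (with an east-west
#' spatial trend on log value), overlays a street grid of road pixels, and
#' rasterizes the result. Road pixels are flagged and carry no value until
#' [fill_roads_idw()] extends parcel values into them.
#'
#' @param spec a [surface_spec()].
#' @return An `exposure_surface` (see [rasterize_parcels()]).
#' @export
generate_surface <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  set.seed(spec$seed)
  rows <- spec$grid_shape[1]; cols <- spec$grid_shape[2]
  ps <- spec$pixel_size

  rects <- partition_rectangles(rows, cols, spec$n_parcels)
  n <- length(rects)
  cat_idx <- sample.int(length(spec$category_set), n, replace = TRUE,
                        prob = spec$category_probs)
  category <- spec$category_set[cat_idx]
  # parcel centroid easting, scaled to [0, 1], drives the value gradient
  xfrac <- vapply(rects, function(r) (r[3] + r[4]) / 2 / cols, 0)
  meanlog <- spec$value_meanlog[cat_idx] + spec$poverty_gradient * xfrac
  value <- stats::rlnorm(n, meanlog = meanlog,
                         sdlog = spec$value_sdlog[cat_idx])

  parcels <- data.frame(
    parcel_id = seq_len(n),
    x0 = vapply(rects, function(r) r[3] * ps, 0),
    x1 = vapply(rects, function(r) r[4] * ps, 0),
    y0 = vapply(rects, function(r) r[1] * ps, 0),
    y1 = vapply(rects, function(r) r[2] * ps, 0),
    value = value,
    category = category,
    stringsAsFactors = FALSE
  )

  road_mask <- matrix(FALSE, rows, cols)
  if (spec$road_fraction > 0) {
    # street spacing s gives road fraction ~ 2/s - 1/s^2
    s <- max(2L, as.integer(round(
      (1 + sqrt(1 - spec$road_fraction)) / spec$road_fraction)))
    if (s <= rows) road_mask[seq(s, rows, by = s), ] <- TRUE
    if (s <= cols) road_mask[, seq(s, cols, by = s)] <- TRUE
  }

  rasterize_parcels(parcels, spec, road_mask = road_mask)
}
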