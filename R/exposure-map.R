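#' Rasterize tax parcels to a 30 m exposure surface
#'
#' Assigns each non-road pixel the taxable value and property category of
#' the parcel containing its center. A pixel center lying exactly on a
#' shared parcel boundary is assigned to the containing parcel with the
#' lowest index. Parcels whose interiors overlap at a pixel center raise an
#' ambiguity error.
#'
#' Grid convention: 0-based, row-major pixels; pixel `(i, j)` covers the
#' half-open square `[origin + 30*(j, i), origin + 30*(j+1, i+1))` in
#' planar meters, with `j` indexing easting (x) and `i` northing (y).
#'
#' @param parcels data.frame with columns `x0, x1, y0, y1` (planar meters),
#'   `value`, `category`; row order defines parcel index.
#' @param spec a [surface_spec()] providing grid shape and pixel size.
#' @param road_mask logical matrix of road pixels (default none).
#' @param origin planar coordinates of the grid corner (pixel (0,0) corner).
#' @param region_mask logical matrix of in-study-region pixels (default all).
#'
#' @return An `exposure_surface`: list with `origin`, `pixel_size`,
#'   `values` (matrix, NA where valueless), `categories` (character matrix),
#'   `road_mask`, `region_mask`, `parcels`, `category_set`.
#' @export
rasterize_parcels <- function(parcels, spec, road_mask = NULL,
                              origin = c(0, 0), region_mask = NULL) {
  rows <- spec$grid_shape[1]; cols <- spec$grid_shape[2]
  ps <- spec$pixel_size
  abort_if(rows < 1 || cols < 1, "grid shape must be positive")
  abort_if(nrow(parcels) < 1, "need at least one parcel")
  if (is.null(road_mask)) road_mask <- matrix(FALSE, rows, cols)
  if (is.null(region_mask)) region_mask <- matrix(TRUE, rows, cols)

  cx <- origin[1] + (seq_len(cols) - 0.5) * ps   # pixel-center eastings
  cy <- origin[2] + (seq_len(rows) - 0.5) * ps   # pixel-center northings

  values <- matrix(NA_real_, rows, cols)
  categories <- matrix(NA_character_, rows, cols)
  owner <- matrix(0L, rows, cols)       # lowest-index containing parcel
  interior_hits <- matrix(0L, rows, cols)

  for (p in seq_len(nrow(parcels))) {
    jj <- which(cx >= parcels$x0[p] & cx <= parcels$x1[p])
    ii <- which(cy >= parcels$y0[p] & cy <= parcels$y1[p])
    if (!length(ii) || !length(jj)) next
    sub <- owner[ii, jj, drop = FALSE]
    take <- sub == 0L
    if (any(take)) {
      sub[take] <- p
      owner[ii, jj] <- sub
    }
    jj_in <- jj[cx[jj] > parcels$x0[p] & cx[jj] < parcels$x1[p]]
    ii_in <- ii[cy[ii] > parcels$y0[p] & cy[ii] < parcels$y1[p]]
    if (length(ii_in) && length(jj_in)) {
      interior_hits[ii_in, jj_in] <- interior_hits[ii_in, jj_in] + 1L
    }
  }
  abort_if(any(interior_hits > 1L),
           "overlapping parcels: a pixel center lies inside more than one parcel")

  assigned <- owner > 0L & !road_mask
  values[assigned] <- parcels$value[owner[assigned]]
  categories[assigned] <- parcels$category[owner[assigned]]

  structure(list(
    origin = as.numeric(origin),
    pixel_size = ps,
    values = values,
    categories = categories,
    road_mask = road_mask,
    region_mask = region_mask,
    parcels = parcels,
    category_set = spec$category_set
  ), class = "exposure_surface")
}

#' @export
print.exposure_surface <- function(x, ...) {
  cat(sprintf(
    "<exposure_surface> %d x %d pixels (%g m), %d parcels, %.1f%% road\n",
    nrow(x$values), ncol(x$values), x$pixel_size, nrow(x$parcels),
    100 * mean(x$road_mask)))
  cat(sprintf("  valued pixels: %d; categories: %s\n",
              sum(!is.na(x$values)), paste(x$category_set, collapse = ", ")))
  invisible(x)
}

#' Extend parcel values into road pixels by inverse-distance weighting
#'
#' Road and sidewalk pixels have no taxable value of their own; each road
#' pixel within `max_dist` (center-to-center) of at least one valued pixel
#' receives the inverse-distance-weighted mean of those values,
#' `sum(w_i v_i) / sum(w_i)` with `w_i = d_i^-power`, and the category of
#' the nearest valued pixel. Road pixels with no valued pixel within
#' `max_dist` stay missing. Non-road pixels are never altered.
#'
#' @param surface an `exposure_surface` from [rasterize_parcels()].
#' @param max_dist maximum fill reach in meters (default 50).
#' @param power inverse-distance exponent (default 2).
#' @return The surface with road pixels filled where possible.
#' @export
fill_roads_idw <- function(surface, max_dist = 50, power = 2) {
  stopifnot(inherits(surface, "exposure_surface"))
  ps <- surface$pixel_size
  rows <- nrow(surface$values); cols <- ncol(surface$values)
  r <- floor(max_dist / ps)
  # candidate pixel offsets within reach, nearest first (deterministic
  # tie-break by row then column offset for the category rule)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off$dist <- ps * sqrt(off$di^2 + off$dj^2)
  off <- off[off$dist > 0 & off$dist <= max_dist, ]
  off <- off[order(off$dist, off$di, off$dj), ]

  donor_values <- surface$values        # pre-fill snapshot: parcels only
  donor_ok <- !is.na(donor_values) & !surface$road_mask

  road_idx <- which(surface$road_mask & surface$region_mask, arr.ind = TRUE)
  for (k in seq_len(nrow(road_idx))) {
    i <- road_idx[k, 1]; j <- road_idx[k, 2]
    num <- 0; den <- 0
    nearest_cat <- NA_character_
    for (o in seq_len(nrow(off))) {
      ii <- i + off$di[o]; jj <- j + off$dj[o]
      if (ii < 1 || ii > rows || jj < 1 || jj > cols) next
      if (!donor_ok[ii, jj]) next
      w <- off$dist[o]^(-power)
      num <- num + w * donor_values[ii, jj]
      den <- den + w
      if (is.na(nearest_cat)) nearest_cat <- surface$categories[ii, jj]
    }
    if (den > 0) {
      surface$values[i, j] <- num / den
      surface$categories[i, j] <- nearest_cat
    }
  }
  surface
}

#' Extract exposure values at GPS points
#'
#' Maps each GPS point to its containing pixel by
#' `floor((coordinate - origin) / pixel_size)` and reads the taxable value
#' and property category there. Points outside the grid, outside the study
#' region, or over pixels with no assignable value yield missing samples
#' with `in_region = FALSE`; this mirrors coding exposure as missing
#' whenever a participant is outside the covered jurisdiction. Every input
#' point yields exactly one sample.
#'
#' @param surface a (road-filled) `exposure_surface`.
#' @param points data.frame of cleaned GPS points with `participant_id`,
#'   `timestamp`, `x_m`, `y_m`.
#' @return data.frame of exposure samples: `participant_id`, `timestamp`,
#'   `value`, `category`, `in_region`.
#' @export
sample_exposure <- function(surface, points) {
  stopifnot(inherits(surface, "exposure_surface"))
  rows <- nrow(surface$values); cols <- ncol(surface$values)
  j <- floor((points$x_m - surface$origin[1]) / surface$pixel_size)
  i <- floor((points$y_m - surface$origin[2]) / surface$pixel_size)
  inside <- i >= 0 & i < rows & j >= 0 & j < cols
  value <- rep(NA_real_, nrow(points))
  category <- rep(NA_character_, nrow(points))
  lin <- (j[inside]) * rows + i[inside] + 1   # column-major linear index
  value[inside] <- surface$values[lin]
  category[inside] <- surface$categories[lin]
  in_reg <- inside
  in_reg[inside] <- surface$region_mask[lin] & !is.na(value[inside])
  value[!in_reg] <- NA_real_
  category[!in_reg] <- NA_character_
  data.frame(
    participant_id = points$participant_id,
    timestamp = points$timestamp,
    value = value,
    category = category,
    in_region = in_reg,
    stringsAsFactors = FALSE
  )
}

#' Write / read an exposure surface as plain-text files
#'
#' The surface serializes to four CSV matrices (`values.csv`,
#' `categories.csv`, `road_mask.csv`, `region_mask.csv`) plus
#' `surface_meta.json` holding the origin, pixel size, grid shape and
#' category legend.
#'
#' @param surface an `exposure_surface`.
#' @param dir output directory (created if needed).
#' @return `write_surface` returns `dir` invisibly; `read_surface` returns
#'   the reconstructed `exposure_surface` (without the parcel table).
#' @export
write_surface <- function(surface, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mat <- function(m, file) {
    utils::write.table(m, file.path(dir, file), sep = ",",
                       row.names = FALSE, col.names = FALSE, na = "")
  }
  write_mat(surface$values, "values.csv")
  write_mat(surface$categories, "categories.csv")
  write_mat(surface$road_mask * 1L, "road_mask.csv")
  write_mat(surface$region_mask * 1L, "region_mask.csv")
  meta <- list(origin = surface$origin, pixel_size = surface$pixel_size,
               grid_shape = dim(surface$values),
               category_set = surface$category_set)
  jsonlite::write_json(meta, file.path(dir, "surface_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_surface
#' @export
read_surface <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "surface_meta.json"),
                              simplifyVector = TRUE)
  read_mat <- function(file, mode) {
    m <- as.matrix(utils::read.table(file.path(dir, file), sep = ",",
                                     header = FALSE, na.strings = "",
                                     colClasses = mode))
    dimnames(m) <- NULL
    m
  }
  structure(list(
    origin = as.numeric(meta$origin),
    pixel_size = meta$pixel_size,
    values = read_mat("values.csv", "numeric"),
    categories = read_mat("categories.csv", "character"),
    road_mask = read_mat("road_mask.csv", "integer") == 1L,
    region_mask = read_mat("region_mask.csv", "integer") == 1L,
    parcels = NULL,
    category_set = meta$category_set
  ), class = "exposure_surface")
}
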