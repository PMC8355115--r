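# Equal-area gridding: Lambert azimuthal equal-area projection on the
# authalic sphere, half-open cell binning, per-OTU binarized occurrence
# distributions, and the overlay (point-to-grid) fraction surface.

AUTHALIC_R_KM <- 6371.0072

#' Grid specification for the analysis extent
#'
#' An equal-area grid of square cells in the Lambert azimuthal equal-area
#' (LAEA) plane.  The default covers a 6000 km by 4000 km box centered on
#' the conterminous United States with 250-km cells (24 columns by 16 rows).
#'
#' @param cell_km cell side length in km (default 250).
#' @param lon0,lat0 projection center in degrees (default -98, 39.5).
#' @param width_km,height_km extent side lengths in km; must be integer
#'   multiples of `cell_km`.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(cell_km = 250, lon0 = -98, lat0 = 39.5,
                      width_km = 6000, height_km = 4000) {
  stopifnot(cell_km > 0,
            width_km %% cell_km == 0, height_km %% cell_km == 0)
  structure(list(cell_km = cell_km, lon0 = lon0, lat0 = lat0,
                 x0 = -width_km / 2, y0 = -height_km / 2,
                 ncol = as.integer(width_km / cell_km),
                 nrow = as.integer(height_km / cell_km)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %g km, LAEA center (%g, %g)\n",
    x$nrow, x$ncol, x$cell_km, x$lon0, x$lat0))
  invisible(x)
}

#' Forward LAEA projection
#'
#' Lambert azimuthal equal-area projection on the authalic sphere
#' (R = 6371.0072 km), centered at the grid's projection center.  The
#' antipode of the center is not projectable.
#'
#' @param lon,lat coordinates in degrees (vectors allowed).
#' @param spec a [grid_spec()].
#' @return data.frame with columns `x_km`, `y_km`.
#' @export
project_laea <- function(lon, lat, spec = grid_spec()) {
  stopifnot(all(lat >= -90 & lat <= 90, na.rm = TRUE),
            all(lon >= -180 & lon <= 180, na.rm = TRUE))
  phi <- lat * pi / 180; phi0 <- spec$lat0 * pi / 180
  dlam <- (lon - spec$lon0) * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dlam)
  if (any(denom < 1e-12, na.rm = TRUE))
    stop("cannot project the antipode of the grid center")
  k <- sqrt(2 / denom)
  data.frame(x_km = AUTHALIC_R_KM * k * cos(phi) * sin(dlam),
             y_km = AUTHALIC_R_KM * k *
               (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dlam)))
}

#' Inverse LAEA projection
#'
#' @param x_km,y_km planar coordinates in km.
#' @param spec a [grid_spec()].
#' @return data.frame with columns `lon`, `lat` in degrees.
#' @export
inverse_laea <- function(x_km, y_km, spec = grid_spec()) {
  phi0 <- spec$lat0 * pi / 180
  rho <- sqrt(x_km^2 + y_km^2)
  c_ang <- 2 * asin(pmin(1, rho / (2 * AUTHALIC_R_KM)))
  lat <- ifelse(rho < 1e-12, spec$lat0,
                asin(cos(c_ang) * sin(phi0) +
                       y_km * sin(c_ang) * cos(phi0) / rho) * 180 / pi)
  lon <- ifelse(rho < 1e-12, spec$lon0,
                spec$lon0 + atan2(x_km * sin(c_ang),
                                  rho * cos(phi0) * cos(c_ang) -
                                    y_km * sin(phi0) * sin(c_ang)) * 180 / pi)
  data.frame(lon = lon, lat = lat)
}

#' Map planar points to grid cells
#'
#' Half-open binning: cell `(r, c)` covers
#' `[x0 + c*cell, x0 + (c+1)*cell) x [y0 + r*cell, y0 + (r+1)*cell)` with
#' 0-based indices, so a point exactly on an interior edge belongs to the
#' higher-index cell.  Points outside the extent get `NA` (off-grid) and are
#' excluded from all counts.
#'
#' @param x_km,y_km planar coordinates in km.
#' @param spec a [grid_spec()].
#' @return data.frame with integer columns `row`, `col` (`NA` off-grid).
#' @export
cell_of <- function(x_km, y_km, spec = grid_spec()) {
  col <- floor((x_km - spec$x0) / spec$cell_km)
  row <- floor((y_km - spec$y0) / spec$cell_km)
  off <- col < 0 | col >= spec$ncol | row < 0 | row >= spec$nrow
  col[off] <- NA_integer_; row[off] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Geographic centroids of grid cells
#'
#' @param row,col 0-based cell indices.
#' @param spec a [grid_spec()].
#' @return data.frame with `lon`, `lat` of each cell center.
#' @export
cell_centroid <- function(row, col, spec = grid_spec()) {
  inverse_laea(spec$x0 + (col + 0.5) * spec$cell_km,
               spec$y0 + (row + 0.5) * spec$cell_km, spec)
}

#' Binarized grid distribution of one OTU
#'
#' The occurrence records of every species assigned to the OTU are pooled
#' (merged before thresholding), binned into grid cells, and a cell is
#' designated positive when the pooled count reaches `min_occurrences`
#' (default 2).  An OTU with no positive cell has an empty distribution and
#' is not a "mapped OTU".
#'
#' @param species character vector of binomials assigned to the OTU.
#' @param store an `occurrence_store`.
#' @param spec a [grid_spec()].
#' @param seed seed forwarded to [query_occurrences()] for over-cap
#'   subsampling.
#' @param min_occurrences per-cell positivity threshold (default 2).
#' @param otu_id identifier carried into the result.
#' @return list with `otu_id` and `positive_cells` (data.frame `row`, `col`).
#' @export
otu_distribution <- function(species, store, spec = grid_spec(), seed = 1L,
                             min_occurrences = 2L, otu_id = NA_character_) {
  stopifnot(length(species) >= 1)
  recs <- do.call(rbind, lapply(species, function(sp)
    query_occurrences(store, sp, seed = seed)))
  if (is.null(recs) || !nrow(recs))
    return(list(otu_id = otu_id,
                positive_cells = data.frame(row = integer(0),
                                            col = integer(0))))
  xy <- project_laea(recs$lon, recs$lat, spec)
  cells <- cell_of(xy$x_km, xy$y_km, spec)
  cells <- cells[!is.na(cells$row), , drop = FALSE]
  if (!nrow(cells))
    return(list(otu_id = otu_id,
                positive_cells = data.frame(row = integer(0),
                                            col = integer(0))))
  counts <- stats::aggregate(n ~ row + col,
                             cbind(cells, n = 1L), FUN = sum)
  pos <- counts[counts$n >= min_occurrences, c("row", "col"), drop = FALSE]
  pos <- pos[order(pos$row, pos$col), , drop = FALSE]
  rownames(pos) <- NULL
  list(otu_id = otu_id, positive_cells = pos)
}

#' Overlay per-OTU distributions into the point-to-grid surface
#'
#' For each grid cell, the fraction of the sample's mapped OTUs (those with
#' a non-empty binarized distribution) whose distribution is positive in
#' that cell.  Widely distributed (cosmopolitan) OTUs contribute a uniform
#' `1/n` everywhere and so cannot dominate any region.
#'
#' @param distributions list of results from [otu_distribution()]; empty
#'   distributions are ignored.
#' @param spec a [grid_spec()].
#' @return an object of class `grid_surface` with fields `spec`, `values`
#'   (an `nrow x ncol` matrix of fractions) and `n_otus`.
#' @export
overlay <- function(distributions, spec = grid_spec()) {
  nonempty <- Filter(function(d) nrow(d$positive_cells) > 0, distributions)
  if (!length(nonempty)) stop("no mapped OTUs")
  counts <- matrix(0L, spec$nrow, spec$ncol)
  for (d in nonempty) {
    idx <- cbind(d$positive_cells$row + 1L, d$positive_cells$col + 1L)
    counts[idx] <- counts[idx] + 1L
  }
  structure(list(spec = spec,
                 values = counts / length(nonempty),
                 n_otus = length(nonempty)),
            class = "grid_surface")
}

#' @export
print.grid_surface <- function(x, ...) {
  cat(sprintf(
    "<grid_surface> %d x %d cells, %d mapped OTUs, %d positive cells\n",
    x$spec$nrow, x$spec$ncol, x$n_otus, sum(x$values > 0)))
  invisible(x)
}

#' Flatten a grid surface to a data.frame
#'
#' One row per grid cell with 0-based indices, geographic centroid,
#' fraction, and the integer OTU count the fraction encodes.
#'
#' @param surface a `grid_surface`.
#' @param drop_zero drop zero-valued cells (default `FALSE`).
#' @return data.frame `row`, `col`, `centroid_lon`, `centroid_lat`,
#'   `fraction`, `count`.
#' @export
surface_to_df <- function(surface, drop_zero = FALSE) {
  spec <- surface$spec
  grid <- expand.grid(row = 0:(spec$nrow - 1), col = 0:(spec$ncol - 1))
  cen <- cell_centroid(grid$row, grid$col, spec)
  out <- data.frame(grid,
                    centroid_lon = cen$lon, centroid_lat = cen$lat,
                    fraction = surface$values[cbind(grid$row + 1,
                                                    grid$col + 1)])
  out$count <- as.integer(round(out$fraction * surface$n_otus))
  if (drop_zero) out <- out[out$fraction > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a grid surface
#'
#' Writes the flat CSV form and/or GeoJSON cell polygons (with `fraction`
#' and `count` properties).
#'
#' @param surface a `grid_surface`.
#' @param csv_path,geojson_path output paths (`NULL` to skip either).
#' @return invisibly, the flat data.frame.
#' @export
write_surface <- function(surface, csv_path = NULL, geojson_path = NULL) {
  df <- surface_to_df(surface)
  if (!is.null(csv_path))
    utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(geojson_path))
    writeLines(surface_geojson(surface), geojson_path)
  invisible(df)
}

surface_geojson <- function(surface) {
  spec <- surface$spec
  df <- surface_to_df(surface, drop_zero = TRUE)
  feats <- vapply(seq_len(nrow(df)), function(i) {
    r <- df$row[i]; c <- df$col[i]
    xs <- spec$x0 + c(c, c + 1, c + 1, c, c) * spec$cell_km
    ys <- spec$y0 + c(r, r, r + 1, r + 1, r) * spec$cell_km
    ll <- inverse_laea(xs, ys, spec)
    ring <- paste(sprintf("[%.6f,%.6f]", ll$lon, ll$lat), collapse = ",")
    sprintf(paste0(
      '{"type":"Feature","properties":{"row":%d,"col":%d,',
      '"fraction":%.10g,"count":%d},"geometry":',
      '{"type":"Polygon","coordinates":[[%s]]}}'),
      r, c, df$fraction[i], df$count[i], ring)
  }, "")
  c('{"type":"FeatureCollection","features":[',
    paste(feats, collapse = ",\n"), "]}")
}
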