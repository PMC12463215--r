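#' Regular longitude-latitude grid specification
#'
#' Defines a global grid of cell centers. Longitude is periodic (wraps at
#' 180/-180); latitude is not (no neighbors beyond the poles). Rows run from
#' north to south, columns from west to east.
#'
#' @param lon_res Cell width in degrees longitude; must divide 360.
#' @param lat_res Cell height in degrees latitude; must divide 180.
#' @return An object of class `grid_spec` with cell-center axes `lon`
#'   (length 360/lon_res) and `lat` (length 180/lat_res, decreasing from
#'   north), and the counts `nlon`, `nlat`.
#' @export
grid_spec <- function(lon_res = 2, lat_res = 2) {
  if (360 %% lon_res != 0 || 180 %% lat_res != 0)
    stop("lon_res must divide 360 and lat_res must divide 180")
  nlon <- as.integer(360 / lon_res)
  nlat <- as.integer(180 / lat_res)
  if (nlon < 4 || nlat < 4)
    stop("degenerate grid: need at least 4x4 cells")
  structure(list(
    lon_res = lon_res, lat_res = lat_res,
    nlon = nlon, nlat = nlat,
    lon = seq(-180 + lon_res / 2, 180 - lon_res / 2, by = lon_res),
    lat = seq(90 - lat_res / 2, -90 + lat_res / 2, by = -lat_res)
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells (%g deg lon x %g deg lat)\n",
              x$nlat, x$nlon, x$lon_res, x$lat_res))
  invisible(x)
}

EARTH_RADIUS_KM <- 6371

#' Great-circle distance between points on the sphere
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in degrees (vectorized).
#' @return Distance in km.
#' @export
gc_distance <- function(lon1, lat1, lon2, lat2) {
  d2r <- pi / 180
  dlat <- (lat2 - lat1) * d2r
  dlon <- (lon2 - lon1) * d2r
  a <- sin(dlat / 2)^2 + cos(lat1 * d2r) * cos(lat2 * d2r) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Cell areas of a grid
#'
#' Spherical band areas: proportional to cos(latitude) up to the band-width
#' correction, exact on the sphere.
#'
#' @param grid A `grid_spec`.
#' @return Vector of cell areas in m^2, one per latitude row (constant along
#'   a row).
#' @export
cell_areas <- function(grid) {
  d2r <- pi / 180
  h <- grid$lat_res / 2
  r_m <- EARTH_RADIUS_KM * 1000
  r_m^2 * (grid$lon_res * d2r) *
    (sin((grid$lat + h) * d2r) - sin((grid$lat - h) * d2r))
}

#' Matrix of cell areas (nlat x nlon)
#' @param grid A `grid_spec`.
#' @return Matrix of areas in m^2.
#' @export
cell_area_matrix <- function(grid) {
  matrix(cell_areas(grid), nrow = grid$nlat, ncol = grid$nlon)
}

# 8-neighborhood offsets (row, col)
NEIGH8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Neighbor linear indices of every cell
#'
#' Longitude wraps; latitude is clamped at the poles (missing neighbors are
#' NA). Linear indices are column-major over an nlat x nlon matrix.
#'
#' @param grid A `grid_spec`.
#' @return Integer matrix (ncell x 8) of neighbor indices, NA where a
#'   neighbor would lie beyond a pole.
#' @keywords internal
neighbor_index <- function(grid) {
  nlat <- grid$nlat; nlon <- grid$nlon
  rows <- rep(seq_len(nlat), times = nlon)
  cols <- rep(seq_len(nlon), each = nlat)
  out <- matrix(NA_integer_, nrow = nlat * nlon, ncol = 8)
  for (k in seq_len(8)) {
    rr <- rows + NEIGH8[k, 1]
    cc <- ((cols - 1 + NEIGH8[k, 2]) %% nlon) + 1
    ok <- rr >= 1 & rr <= nlat
    out[ok, k] <- (cc[ok] - 1L) * nlat + rr[ok]
  }
  out
}

# Circularly shift a matrix by (dr, dc): rows clamped (NA padding), columns wrap.
shift_matrix <- function(m, dr, dc) {
  nlat <- nrow(m); nlon <- ncol(m)
  out <- matrix(NA_real_, nlat, nlon)
  src_rows <- seq_len(nlat) + dr
  ok <- src_rows >= 1 & src_rows <= nlat
  src_cols <- ((seq_len(nlon) - 1 + dc) %% nlon) + 1
  out[ok, ] <- m[src_rows[ok], src_cols]
  out
}
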