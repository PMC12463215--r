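#' Topographic position index over an annular neighborhood
#'
#' TPI of cell i is its elevation minus the mean elevation of the cells in an
#' annulus around it (Chebyshev radius `inner < d <= outer`). Sea cells are
#' excluded from the mean; longitude wraps, latitude is clamped at the poles.
#' Positive values mark ridges and peaks, negative values valleys.
#'
#' @param elevation Elevation matrix (m); sea cells may be NA.
#' @param land Logical land mask of the same shape.
#' @param inner,outer Annulus radii in cells, `0 <= inner < outer`.
#' @return Matrix of TPI (m); NA on sea cells and on land cells with no valid
#'   neighbor in the annulus.
#' @export
compute_tpi <- function(elevation, land, inner = 0, outer = 1) {
  stopifnot(inner >= 0, inner < outer)
  z <- ifelse(land, elevation, NA_real_)
  acc <- matrix(0, nrow(z), ncol(z))
  cnt <- matrix(0L, nrow(z), ncol(z))
  for (dr in -outer:outer) {
    for (dc in -outer:outer) {
      d <- max(abs(dr), abs(dc))
      if (d <= inner || d > outer) next
      s <- shift_matrix(z, dr, dc)
      ok <- !is.na(s)
      acc[ok] <- acc[ok] + s[ok]
      cnt[ok] <- cnt[ok] + 1L
    }
  }
  out <- matrix(NA_real_, nrow(z), ncol(z))
  valid <- land & cnt > 0
  out[valid] <- z[valid] - acc[valid] / cnt[valid]
  out
}

#' Standardized TPI
#'
#' Scales a TPI layer to `100 * (TPI - mean) / sd`, with mean and standard
#' deviation taken over all valid (land) cells, so layers computed at
#' different neighborhood scales become comparable.
#'
#' @param tpi TPI matrix (NA outside land).
#' @return Matrix of standardized scores with attribute `flat = TRUE` when
#'   the field had zero variance (all zeros returned in that case).
#' @export
standardize_tpi <- function(tpi) {
  v <- tpi[!is.na(tpi)]
  if (length(v) < 2) {   # degenerate field: nothing to scale against
    out <- ifelse(is.na(tpi), NA_real_, 0)
    attr(out, "flat") <- TRUE
    return(out)
  }
  s <- stats::sd(v)
  if (s == 0 || !is.finite(s)) {
    out <- ifelse(is.na(tpi), NA_real_, 0)
    attr(out, "flat") <- TRUE
    return(out)
  }
  out <- 100 * (tpi - mean(v)) / s
  attr(out, "flat") <- FALSE
  out
}

#' Terrain slope in degrees
#'
#' Slope of a cell is `atan` of the maximum absolute elevation gradient to its
#' 8 land neighbors, with horizontal distances taken as great-circle distances
#' between cell centers. Isolated land cells (no land neighbor) get slope 0
#' and are flagged.
#'
#' @param elevation Elevation matrix (m).
#' @param land Logical land mask.
#' @param grid The `grid_spec` (for cell-center distances).
#' @return Matrix of slopes in degrees (NA on sea) with attribute `isolated`,
#'   a logical matrix marking flagged cells.
#' @export
compute_slope <- function(elevation, land, grid) {
  z <- ifelse(land, elevation, NA_real_)
  nlat <- grid$nlat; nlon <- grid$nlon
  best <- matrix(0, nlat, nlon)
  seen <- matrix(FALSE, nlat, nlon)
  latm <- matrix(grid$lat, nlat, nlon)
  lonm <- matrix(grid$lon, nlat, nlon, byrow = TRUE)
  for (k in seq_len(8)) {
    dr <- NEIGH8[k, 1]; dc <- NEIGH8[k, 2]
    zn <- shift_matrix(z, dr, dc)
    latn <- shift_matrix(latm, dr, dc)
    lonn <- shift_matrix(lonm, dr, dc)
    ok <- !is.na(zn) & !is.na(z)
    dist_m <- gc_distance(lonm[ok], latm[ok], lonn[ok], latn[ok]) * 1000
    g <- abs(z[ok] - zn[ok]) / dist_m
    upd <- g > best[ok]
    tmp <- best[ok]; tmp[upd] <- g[upd]; best[ok] <- tmp
    seen[ok] <- TRUE
  }
  out <- matrix(NA_real_, nlat, nlon)
  out[land] <- atan(best[land]) * 180 / pi
  attr(out, "isolated") <- land & !seen
  out
}

# Lower bounds of slope categories 2..10 (degrees); category 1 is < 0.03.
SLOPE_BOUNDS <- c(0.03, 0.11, 0.3, 0.5, 0.85, 1.65, 2.4, 3.5, 4.5)

#' Hierarchical slope classification (10 categories)
#'
#' Category is the highest class whose inclusive lower bound does not exceed
#' the value: breaks at 0.03, 0.11, 0.3, 0.5, 0.85, 1.65, 2.4, 3.5 and 4.5
#' degrees, so e.g. 0.2 deg is class 3 and exactly 0.03 deg is class 2.
#'
#' @param slope Slope in degrees (vector or matrix; NA passed through).
#' @return Integer categories 1..10, same shape as the input.
#' @export
categorize_slope <- function(slope) {
  out <- slope
  out[] <- vapply(as.vector(slope), function(v) {
    if (is.na(v)) return(NA_integer_)
    1L + sum(v >= SLOPE_BOUNDS)
  }, integer(1))
  out
}

#' Water-flux classification (5 log-spaced categories)
#'
#' Discharge classes on log10(m^3/yr): below 7, 7-8, 8-9, 9-10, and 10 or
#' above (inclusive lower bounds). Zero discharge falls in class 1.
#'
#' @param discharge Discharge in m^3/yr (vector or matrix; NA passed through).
#' @return Integer categories 1..5, same shape as the input.
#' @export
categorize_flux <- function(discharge) {
  if (any(discharge < 0, na.rm = TRUE)) stop("discharge must be nonnegative")
  lg <- suppressWarnings(log10(discharge))  # -Inf at 0 is fine
  out <- discharge
  out[] <- findInterval(as.vector(lg), c(7, 8, 9, 10)) + 1L
  out[is.na(discharge)] <- NA
  out
}

#' Hydrological categories
#'
#' The landscape's hydrological categorization H: the five log-spaced
#' water-discharge classes applied to a discharge field.
#'
#' @inheritParams categorize_flux
#' @return Integer H categories 1..5.
#' @export
hydro_categories <- function(discharge) categorize_flux(discharge)

#' Decile classification of standardized TPI (10 categories)
#'
#' No fixed thresholds exist for TPI, so classes are the deciles of the
#' land-cell distribution of the slice being classified.
#'
#' @param tpi_s Standardized TPI matrix (NA outside land).
#' @return Integer categories 1..10 (NA outside land).
#' @export
categorize_tpi <- function(tpi_s) {
  v <- tpi_s[!is.na(tpi_s)]
  if (length(v) == 0) return(tpi_s)
  br <- unique(stats::quantile(v, probs = seq(0, 1, 0.1), names = FALSE))
  out <- tpi_s
  if (length(br) < 2) {
    out[!is.na(out)] <- 1L
    return(out)
  }
  out[] <- as.integer(cut(as.vector(tpi_s), breaks = br,
                          include.lowest = TRUE, labels = FALSE))
  out
}

#' Physiographic diversity index (Shannon equitability)
#'
#' For every land cell, looks at the square neighborhood of Chebyshev radius
#' `radius` (sea cells excluded, coastlines clip the window), computes the
#' Shannon index `-sum p_k ln p_k` of each categorical layer separately,
#' normalizes each by the log of that layer's total category count (10 for
#' TPI, 10 for slope, 5 for flux), and averages the three equitabilities.
#' The result is bounded in [0, 1]: 0 when all three layers are locally
#' constant, 1 when each layer is uniformly spread over all its classes.
#'
#' @param tpi_cat,slope_cat,flux_cat Integer category matrices (aligned).
#' @param land Logical land mask.
#' @param radius Neighborhood radius in cells (default 1: 3x3 window).
#' @param n_classes Total class counts of the three layers.
#' @return Matrix of phi in [0,1]; NA on sea cells.
#' @export
physiographic_diversity <- function(tpi_cat, slope_cat, flux_cat, land,
                                    radius = 1,
                                    n_classes = c(10, 10, 5)) {
  stopifnot(radius >= 1)
  layers <- list(tpi_cat, slope_cat, flux_cat)
  nlat <- nrow(land); nlon <- ncol(land)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  # stack of shifted copies per layer: neighborhoods as rows
  stacks <- lapply(layers, function(m) {
    m <- ifelse(land, m, NA_real_)
    vapply(seq_len(nrow(offs)),
           function(k) as.vector(shift_matrix(m, offs$dr[k], offs$dc[k])),
           numeric(nlat * nlon))
  })
  shannon_equit <- function(vals, n_cl) {
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(NA_real_)
    p <- tabulate(as.integer(vals), nbins = n_cl)
    p <- p[p > 0] / length(vals)
    -sum(p * log(p)) / log(n_cl)
  }
  out <- matrix(NA_real_, nlat, nlon)
  idx <- which(land)
  for (i in idx) {
    e <- vapply(1:3, function(l) shannon_equit(stacks[[l]][i, ],
                                               n_classes[l]), numeric(1))
    # a layer can be all-NA in the window (e.g. masked TPI on an isolated
    # cell): average over the layers that have observations
    out[i] <- if (all(is.na(e))) 0 else mean(e, na.rm = TRUE)
  }
  out
}

#' All physiography layers for one landscape slice
#'
#' Computes the two-scale standardized TPI (ring of radius 1 and ring of radii
#' 2-3, averaged), slope, the categorical layers, hydrological categories and
#' the physiographic diversity index for the time slice `t_index` of a
#' landscape series.
#'
#' @param series A `landscape_series`.
#' @param t_index Time slice index (1-based).
#' @param phi_radius Neighborhood radius for the diversity index.
#' @return List of class `physiography_layers` with matrices `tpi_fine`,
#'   `tpi_coarse`, `tpi_s`, `slope`, `tpi_cat`, `slope_cat`, `flux_cat`, `H`,
#'   `phi`, and the logical `land`.
#' @export
physiography_layers <- function(series, t_index, phi_radius = 1) {
  land <- series$land[, , t_index]
  elev <- series$elevation[, , t_index]
  disc <- series$discharge[, , t_index]
  tpi_f <- compute_tpi(elev, land, inner = 0, outer = 1)
  tpi_c <- compute_tpi(elev, land, inner = 1, outer = 3)
  tpi_s <- (standardize_tpi(tpi_f) + standardize_tpi(tpi_c)) / 2
  slope <- compute_slope(elev, land, series$grid)
  tpi_cat <- categorize_tpi(tpi_s)
  slope_cat <- categorize_slope(slope)
  flux_cat <- categorize_flux(disc)
  phi <- physiographic_diversity(tpi_cat, slope_cat, flux_cat, land,
                                 radius = phi_radius)
  structure(list(tpi_fine = tpi_f, tpi_coarse = tpi_c, tpi_s = tpi_s,
                 slope = slope, tpi_cat = tpi_cat, slope_cat = slope_cat,
                 flux_cat = flux_cat, H = flux_cat, phi = phi, land = land),
            class = "physiography_layers")
}
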