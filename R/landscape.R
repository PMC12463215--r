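#' World generator configuration
#'
#' Bundles every knob of the synthetic paleo-world generator. Defaults are the
#' reference study conditions: a 2 deg grid, 150 one-Myr steps (ages 150..0 Ma),
#' six drifting continents with a northern land-area excess, one continental
#' fragmentation event, two orogeny pulses, and a transient climate-driven
#' extinction pulse ("pseudo K-Pg") at 66 Ma.
#'
#' @param seed Integer seed; the whole series is deterministic given it.
#' @param n_steps Number of 1-Myr steps; ages run `n_steps..0`.
#' @param lon_res,lat_res Grid resolution in degrees.
#' @param n_continents Number of continental blobs.
#' @param hemisphere_asymmetry In `[0,1]`; 0 places continents symmetrically
#'   about the equator in expectation, larger values shift land north.
#' @param land_fraction Target fraction of global area that is land; sea level
#'   is set per step as the area-weighted quantile of the raw height field.
#' @param orogeny Data frame with columns `time` (Ma, pulse onset), `lat`,
#'   `lon` (center, degrees), `amplitude` (m), `radius` (degrees). Each pulse
#'   grows linearly over 10 Myr then persists.
#' @param fragmentation_times Ages (Ma) at which every continent splits in two.
#' @param kpg_time Age (Ma) of the climate shock; `NULL` or `kpg_severity = 0`
#'   disables it.
#' @param kpg_severity Fractional drop: temperature falls by
#'   `severity * (equator_T - pole_T)` degrees C and precipitation by the
#'   factor `1 - severity`.
#' @param kpg_duration Steps at full severity (default 2).
#' @param kpg_recovery Steps of linear recovery back to baseline (default 5).
#' @param equator_T,pole_T Sea-level zonal temperature endpoints, deg C;
#'   `equator_T > pole_T` required.
#' @param tropics_P,pole_P Zonal precipitation endpoints, m/yr;
#'   `tropics_P > pole_P` required.
#' @param sealevel_amplitude Fractional amplitude of the eustatic sea-level
#'   cycle: the land fraction oscillates by this relative amount
#'   (transgression/regression cycles; 0 disables).
#' @param sealevel_period Period of the sea-level cycle, Myr.
#' @param climate_cycle_amplitude Amplitude (deg C at the equator) of the
#'   long greenhouse-icehouse temperature cycle; amplified toward the poles
#'   by the factor `0.5 + |lat|/90`.
#' @param climate_cycle_period Period of the climate cycle, Myr.
#' @return A list of class `world_config`.
#' @export
world_config <- function(seed = 1, n_steps = 150, lon_res = 2, lat_res = 2,
                         n_continents = 6, hemisphere_asymmetry = 0.5,
                         land_fraction = 0.3,
                         orogeny = data.frame(
                           time = c(100, 45), lat = c(35, 25),
                           lon = c(80, 10), amplitude = c(2000, 2500),
                           radius = c(18, 15)),
                         fragmentation_times = 110,
                         kpg_time = 66, kpg_severity = 0.25,
                         kpg_duration = 2, kpg_recovery = 5,
                         equator_T = 28, pole_T = -25,
                         tropics_P = 2.0, pole_P = 0.3,
                         sealevel_amplitude = 0.15, sealevel_period = 25,
                         climate_cycle_amplitude = 4,
                         climate_cycle_period = 80) {
  grid <- grid_spec(lon_res, lat_res)
  stopifnot(equator_T > pole_T, tropics_P > pole_P,
            hemisphere_asymmetry >= 0, hemisphere_asymmetry <= 1,
            land_fraction > 0, land_fraction < 1, n_steps >= 1)
  structure(list(
    seed = as.integer(seed), n_steps = as.integer(n_steps), grid = grid,
    n_continents = n_continents,
    hemisphere_asymmetry = hemisphere_asymmetry,
    land_fraction = land_fraction,
    orogeny = orogeny, fragmentation_times = fragmentation_times,
    kpg_time = kpg_time, kpg_severity = kpg_severity,
    kpg_duration = kpg_duration, kpg_recovery = kpg_recovery,
    equator_T = equator_T, pole_T = pole_T,
    tropics_P = tropics_P, pole_P = pole_P,
    sealevel_amplitude = sealevel_amplitude,
    sealevel_period = sealevel_period,
    climate_cycle_amplitude = climate_cycle_amplitude,
    climate_cycle_period = climate_cycle_period
  ), class = "world_config")
}

# Severity multiplier of the pseudo-K-Pg shock at a given age.
kpg_factor <- function(cfg, age) {
  if (is.null(cfg$kpg_time) || cfg$kpg_severity == 0) return(0)
  offset <- cfg$kpg_time - age          # steps since onset (ages decrease)
  if (offset < 0) return(0)
  if (offset < cfg$kpg_duration) return(cfg$kpg_severity)
  rec <- offset - cfg$kpg_duration + 1  # 1..kpg_recovery during recovery
  if (rec <= cfg$kpg_recovery)
    return(cfg$kpg_severity * (1 - rec / cfg$kpg_recovery))
  0
}

# Smooth random field on the grid: filtered white noise, longitude-periodic.
smooth_noise <- function(grid, sd = 1, passes = 3) {
  m <- matrix(stats::rnorm(grid$nlat * grid$nlon), grid$nlat, grid$nlon)
  for (p in seq_len(passes)) {
    acc <- m
    cnt <- matrix(1, grid$nlat, grid$nlon)
    for (k in seq_len(8)) {
      s <- shift_matrix(m, NEIGH8[k, 1], NEIGH8[k, 2])
      ok <- !is.na(s)
      acc[ok] <- acc[ok] + s[ok]
      cnt[ok] <- cnt[ok] + 1
    }
    m <- acc / cnt
  }
  m / stats::sd(m) * sd
}

#' Generate a synthetic dynamic world
#'
#' Builds a time series of elevation, temperature, precipitation, water
#' discharge and land-sea mask on a regular grid. Continents are smoothed
#' Gaussian blobs advected by per-continent drift velocities; fragmentation
#' splits each blob in two at configured ages; orogeny pulses add mountain
#' massifs. Sea level is the per-step area-weighted height quantile that keeps
#' the configured land fraction. Temperature is a monotone pole-to-equator
#' zonal profile (no elevational lapse, so the zonal-mean monotonicity holds
#' by construction); precipitation peaks in the tropics with multiplicative
#' terrain noise; both are depressed during the pseudo-K-Pg shock. Discharge
#' is steepest-descent flow accumulation of precipitation.
#'
#' @param config A [world_config()].
#' @return A `landscape_series`: list with `grid`, `times` (ages in Ma,
#'   decreasing), `config`, and arrays `elevation` (m), `temperature` (deg C),
#'   `precipitation` (m/yr), `discharge` (m^3/yr), `land` (logical), each of
#'   dim `c(nlat, nlon, n_times)`. Sea cells carry NA elevation/discharge.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  grid <- config$grid
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n_t <- config$n_steps + 1L
  times <- seq(config$n_steps, 0)
  nlat <- grid$nlat; nlon <- grid$nlon

  # continents: centers, drift velocities, angular radii, amplitudes
  n_c <- config$n_continents
  k_north <- round(n_c * (1 + config$hemisphere_asymmetry) / 2)
  lat0 <- c(stats::runif(k_north, 10, 50),
            stats::runif(n_c - k_north, -50, -10))
  cont <- data.frame(
    lat = lat0,
    lon = stats::runif(n_c, -180, 180),
    vlat = stats::runif(n_c, -0.08, 0.08),
    vlon = stats::runif(n_c, -0.15, 0.15),
    radius = stats::runif(n_c, 28, 40) * sqrt(4 / n_c),
    amp = stats::runif(n_c, 2500, 3500)
  )
  frag_done <- logical(0)

  noise <- smooth_noise(grid, sd = 400)
  areas <- cell_area_matrix(grid)
  latm <- matrix(grid$lat, nlat, nlon)
  lonm <- matrix(grid$lon, nlat, nlon, byrow = TRUE)

  dims <- c(nlat, nlon, n_t)
  elevation <- array(NA_real_, dims)
  temperature <- array(NA_real_, dims)
  precipitation <- array(NA_real_, dims)
  discharge <- array(NA_real_, dims)
  land_arr <- array(FALSE, dims)

  zonal_T0 <- config$equator_T +
    (config$pole_T - config$equator_T) * (abs(grid$lat) / 90)^1.5
  zonal_P0 <- config$pole_P +
    (config$tropics_P - config$pole_P) * exp(-(grid$lat / 30)^2)
  p_noise <- smooth_noise(grid, sd = 0.15)

  for (ti in seq_len(n_t)) {
    age <- times[ti]

    if (ti > 1) {  # advance drift by one step (1 Myr)
      cont$lat <- pmax(-85, pmin(85, cont$lat + cont$vlat))
      cont$lon <- ((cont$lon + cont$vlon + 180) %% 360) - 180
    }
    # fragmentation events (each continent splits once per event)
    for (ft in config$fragmentation_times) {
      key <- paste0("f", ft)
      if (age <= ft && !(key %in% frag_done)) {
        frag_done <- c(frag_done, key)
        halves <- cont
        off <- 0.35 * cont$radius
        cont$lon <- cont$lon - off / 2
        halves$lon <- halves$lon + off / 2
        cont$radius <- cont$radius / sqrt(2)
        halves$radius <- halves$radius / sqrt(2)
        halves$vlon <- halves$vlon + 0.08
        cont$vlon <- cont$vlon - 0.08
        cont <- rbind(cont, halves)
      }
    }

    clat <- cont$lat
    clon <- cont$lon

    height <- noise
    for (ci in seq_len(nrow(cont))) {
      ang <- gc_distance(lonm, latm, clon[ci], clat[ci]) /
        (EARTH_RADIUS_KM * pi / 180)   # angular distance in degrees
      height <- height + cont$amp[ci] * exp(-(ang / cont$radius[ci])^2)
    }
    # orogeny pulses: grow over 10 Myr after onset, then persist
    if (nrow(config$orogeny) > 0) {
      for (oi in seq_len(nrow(config$orogeny))) {
        o <- config$orogeny[oi, ]
        growth <- min(1, max(0, (o$time - age) / 10))
        if (growth > 0) {
          ang <- gc_distance(lonm, latm, o$lon, o$lat) /
            (EARTH_RADIUS_KM * pi / 180)
          height <- height + growth * o$amplitude * exp(-(ang / o$radius)^2)
        }
      }
    }

    lf_t <- config$land_fraction *
      (1 + config$sealevel_amplitude * sin(2 * pi * age / config$sealevel_period))
    lf_t <- min(0.95, max(0.05, lf_t))
    sl <- weighted_quantile(as.vector(height), as.vector(areas), 1 - lf_t)
    land <- height > sl
    elev <- ifelse(land, height - sl, NA_real_)

    s <- kpg_factor(config, age)
    wiggle <- config$climate_cycle_amplitude *
      sin(2 * pi * age / config$climate_cycle_period) *
      (0.5 + abs(grid$lat) / 90)
    Tz <- zonal_T0 + wiggle - s * (config$equator_T - config$pole_T)
    temp <- matrix(Tz, nlat, nlon)
    prec <- pmax(0, matrix(zonal_P0, nlat, nlon) * (1 + p_noise)) * (1 - s)

    disc <- flow_accumulate(elev, prec, areas, land)

    elevation[, , ti] <- elev
    temperature[, , ti] <- temp
    precipitation[, , ti] <- prec
    discharge[, , ti] <- disc
    land_arr[, , ti] <- land
  }

  # orient the world: hemispheres are exchangeable labels, so a positive
  # asymmetry guarantees the land-rich hemisphere (at the first slice) is
  # labelled north
  if (config$hemisphere_asymmetry > 0) {
    north <- grid$lat > 0
    south <- grid$lat < 0   # the equator row belongs to neither
    l1 <- land_arr[, , 1]
    if (sum(areas[north, ] * l1[north, ]) <
        sum(areas[south, ] * l1[south, ])) {
      flip <- rev(seq_len(nlat))
      elevation <- elevation[flip, , , drop = FALSE]
      temperature <- temperature[flip, , , drop = FALSE]
      precipitation <- precipitation[flip, , , drop = FALSE]
      discharge <- discharge[flip, , , drop = FALSE]
      land_arr <- land_arr[flip, , , drop = FALSE]
    }
  }

  structure(list(grid = grid, times = times, config = config,
                 elevation = elevation, temperature = temperature,
                 precipitation = precipitation, discharge = discharge,
                 land = land_arr),
            class = "landscape_series")
}

#' @export
print.landscape_series <- function(x, ...) {
  cat(sprintf(
    "<landscape_series> %d x %d grid, %d slices (ages %g..%g Ma), land %.1f%%\n",
    x$grid$nlat, x$grid$nlon, length(x$times),
    max(x$times), min(x$times), 100 * mean(x$land)))
  invisible(x)
}

# Area-weighted quantile (type-1 step interpolation).
weighted_quantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= p)[1]]
}

#' Steepest-descent flow accumulation
#'
#' Single-flow-direction routing: every land cell passes its accumulated flux
#' to its lowest strictly-lower 8-neighbor; cells with no lower land neighbor
#' are sinks (pits/lake proxies) and retain their flux. An all-flat landscape
#' therefore returns the local input everywhere.
#'
#' @param elevation Matrix of elevations (m); sea cells may be NA.
#' @param precipitation Matrix of precipitation (m/yr).
#' @param areas Matrix (or per-row vector) of cell areas (m^2).
#' @param land Logical matrix; only land cells carry flow.
#' @return Matrix of discharge (m^3/yr); NA on sea cells.
#' @export
flow_accumulate <- function(elevation, precipitation, areas, land) {
  nlat <- nrow(elevation); nlon <- ncol(elevation)
  if (is.null(dim(areas))) areas <- matrix(areas, nlat, nlon)
  stopifnot(all(dim(precipitation) == c(nlat, nlon)),
            all(dim(land) == c(nlat, nlon)))
  grid_like <- list(nlat = nlat, nlon = nlon)
  nb <- neighbor_index(grid_like)
  flux <- ifelse(land, precipitation * areas, NA_real_)
  z <- ifelse(land, elevation, -Inf)
  land_idx <- which(land)
  ord <- land_idx[order(z[land_idx], decreasing = TRUE)]
  for (i in ord) {
    nbi <- nb[i, ]
    nbi <- nbi[!is.na(nbi)]
    nbi <- nbi[land[nbi]]
    if (length(nbi) == 0) next
    drops <- z[i] - z[nbi]
    j <- nbi[which.max(drops)]
    if (z[j] < z[i]) flux[j] <- flux[j] + flux[i]
  }
  flux
}

#' Write a landscape series as a CSV stack
#'
#' One CSV file per variable per time slice plus a `meta.csv` describing the
#' grid and time axis. Values are written with 7 significant digits, so a
#' round-trip reproduces the series to better than 1e-5 relative error.
#'
#' @param series A `landscape_series`.
#' @param path Directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(series, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- series$grid
  meta <- data.frame(key = c("lon_res", "lat_res", "n_times", "times"),
                     value = c(g$lon_res, g$lat_res, length(series$times),
                               paste(series$times, collapse = ";")))
  utils::write.csv(meta, file.path(path, "meta.csv"), row.names = FALSE)
  for (var in c("elevation", "temperature", "precipitation",
                "discharge", "land")) {
    a <- series[[var]]
    for (ti in seq_along(series$times)) {
      m <- a[, , ti]
      fn <- file.path(path, sprintf("%s_%04d.csv", var, series$times[ti]))
      if (var == "land") {
        utils::write.table(m * 1L, fn, sep = ",", row.names = FALSE,
                           col.names = FALSE)
      } else {
        utils::write.table(signif(m, 7), fn, sep = ",", row.names = FALSE,
                           col.names = FALSE)
      }
    }
  }
  invisible(path)
}

#' Read a landscape series written by [write_landscape()]
#'
#' @param path Directory containing `meta.csv` and per-variable slice files.
#' @return A `landscape_series` (without the generating `config`).
#' @export
read_landscape <- function(path) {
  mf <- file.path(path, "meta.csv")
  if (!file.exists(mf)) stop("not a landscape directory: missing meta.csv")
  meta <- utils::read.csv(mf, stringsAsFactors = FALSE)
  val <- function(k) meta$value[match(k, meta$key)]
  grid <- grid_spec(as.numeric(val("lon_res")), as.numeric(val("lat_res")))
  times <- as.numeric(strsplit(val("times"), ";")[[1]])
  dims <- c(grid$nlat, grid$nlon, length(times))
  out <- list(grid = grid, times = times, config = NULL)
  for (var in c("elevation", "temperature", "precipitation",
                "discharge", "land")) {
    a <- array(NA_real_, dims)
    for (ti in seq_along(times)) {
      fn <- file.path(path, sprintf("%s_%04d.csv", var, times[ti]))
      if (!file.exists(fn))
        stop(sprintf("landscape stack is missing variable '%s' (file %s)",
                     var, basename(fn)))
      m <- as.matrix(utils::read.table(fn, sep = ","))
      if (!all(dim(m) == dims[1:2]))
        stop(sprintf("inconsistent shape for variable '%s'", var))
      dimnames(m) <- NULL
      a[, , ti] <- m
    }
    out[[var]] <- if (var == "land") a == 1 else a
  }
  class(out) <- "landscape_series"
  out
}

# Save/restore .Random.seed so generators don't perturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
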