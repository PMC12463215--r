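#' Per-cell speciation/extinction/net/turnover surfaces
#'
#' Converts a simulation's event log into rate grids. An origination is
#' attributed to every cell of the founding cluster with weight `1/n_cells`
#' (so summing a step's surface recovers the global count); an extinction is
#' attributed to the species' last occupied cells likewise. Net
#' diversification is speciation minus extinction; turnover is
#' `(speciation + extinction) / richness`, masked (NA) where richness is 0.
#' The function also audits the bookkeeping
#' `S(t+1) = S(t) + originations - extinctions` against the richness record
#' and errors on any inconsistency.
#'
#' @param record A `simulation_record`.
#' @return List of arrays (`speciation`, `extinction`, `net`, `turnover`),
#'   each `nlat x nlon x n_times`.
#' @export
rates <- function(record) {
  dims <- dim(record$richness)
  spec <- array(0, dims)
  ext <- array(0, dims)
  ev <- record$events
  for (i in seq_len(nrow(ev))) {
    cells <- record$event_cells[[i]]
    w <- 1 / length(cells)
    sl <- ev$step[i]
    if (ev$type[i] == "origination") {
      m <- spec[, , sl]; m[cells] <- m[cells] + w; spec[, , sl] <- m
    } else {
      m <- ext[, , sl]; m[cells] <- m[cells] + w; ext[, , sl] <- m
    }
  }
  # bookkeeping audit: global extant count vs cumulative events
  n_t <- dims[3]
  extant <- vapply(seq_len(n_t), function(ti) {
    age <- record$times[ti]
    sum(record$species$origin_age >= age &
          (is.na(record$species$extinct_age) |
             record$species$extinct_age < age))
  }, numeric(1))
  orig_by_step <- tabulate(ev$step[ev$type == "origination"], nbins = n_t)
  ext_by_step <- tabulate(ev$step[ev$type == "extinction"], nbins = n_t)
  s_traj <- cumsum(c(1, (orig_by_step - ext_by_step)[-1]))
  if (any(extant != s_traj))
    stop("bookkeeping integrity error: extant counts do not match events")
  turnover <- array(NA_real_, dims)
  pos <- record$richness > 0
  turnover[pos] <- (spec[pos] + ext[pos]) / record$richness[pos]
  list(speciation = spec, extinction = ext, net = spec - ext,
       turnover = turnover)
}

#' Latitudinal profile of a metric
#'
#' Collapses a metric stack to latitude bands: for each band (one per
#' distinct cell-center latitude) the cos(lat)-area-weighted mean over land
#' cells, per time step. Optionally drops the spin-up steps and normalizes
#' the whole profile by its maximum.
#'
#' @param record A `simulation_record` (supplies land masks, grid, spinup).
#' @param metric Either the string "richness" or a metric array of the same
#'   dimensions (e.g. one of the [rates()] surfaces).
#' @param normalize Divide by the profile's maximum (default TRUE).
#' @param exclude_spinup Drop the first `record$spinup` steps (default TRUE).
#' @return Matrix (n_bands x n_kept_steps) with rownames the band latitudes
#'   and colnames the ages; NA where a band has no land.
#' @export
latitudinal_profile <- function(record, metric = "richness",
                                normalize = TRUE, exclude_spinup = TRUE) {
  a <- if (is.character(metric)) record[[metric]] else metric
  stopifnot(all(dim(a) == dim(record$land)))
  n_t <- dim(a)[3]
  keep <- if (exclude_spinup) (record$spinup + 1):n_t else seq_len(n_t)
  lats <- record$grid$lat
  w <- cos(lats * pi / 180)
  out <- matrix(NA_real_, length(lats), length(keep))
  for (j in seq_along(keep)) {
    ti <- keep[j]
    land <- record$land[, , ti]
    m <- a[, , ti]
    for (r in seq_along(lats)) {
      sel <- land[r, ] & !is.na(m[r, ])
      if (any(sel)) out[r, j] <- sum(m[r, sel] * w[r]) / (sum(sel) * w[r])
    }
  }
  if (normalize) {
    mx <- max(out, na.rm = TRUE)
    if (is.finite(mx) && mx > 0) out <- out / mx
  }
  rownames(out) <- lats
  colnames(out) <- record$times[keep]
  out
}

#' Average metrics over an ensemble of simulations
#'
#' Arithmetic mean of richness and rate surfaces across records sharing one
#' grid and time axis. Averaging happens before any normalization — the mean
#' of normalized surfaces is not the normalized mean.
#'
#' @param records List of `simulation_record`s on identical grids/time axes.
#' @return A list shaped like a `simulation_record` (class
#'   `ensemble_summary`) with averaged `richness`, `speciation`,
#'   `extinction`, `net`, `turnover` arrays plus shared `land`, `grid`,
#'   `times`, `spinup`.
#' @export
ensemble_average <- function(records) {
  stopifnot(length(records) >= 1)
  ref <- records[[1]]
  for (r in records) {
    if (!identical(dim(r$richness), dim(ref$richness)) ||
        !identical(r$times, ref$times))
      stop("records have mismatched grids or time axes")
  }
  acc <- list(richness = array(0, dim(ref$richness)))
  rate_names <- c("speciation", "extinction", "net", "turnover")
  for (nm in rate_names) acc[[nm]] <- array(0, dim(ref$richness))
  turn_n <- array(0, dim(ref$richness))
  for (r in records) {
    rr <- rates(r)
    acc$richness <- acc$richness + r$richness
    for (nm in c("speciation", "extinction", "net"))
      acc[[nm]] <- acc[[nm]] + rr[[nm]]
    tv <- rr$turnover
    ok <- !is.na(tv)
    acc$turnover[ok] <- acc$turnover[ok] + tv[ok]
    turn_n[ok] <- turn_n[ok] + 1
  }
  n <- length(records)
  out <- list(richness = acc$richness / n,
              speciation = acc$speciation / n,
              extinction = acc$extinction / n,
              net = acc$net / n,
              turnover = ifelse(turn_n > 0, acc$turnover / turn_n, NA),
              land = ref$land, grid = ref$grid, times = ref$times,
              spinup = ref$spinup)
  class(out) <- c("ensemble_summary", "simulation_record")
  out
}

#' Spearman correlation between two richness grids
#'
#' Rank correlation over the cells valid (non-NA) in both grids, restricted
#' to a latitude window (default -54..71 degrees, the range over which
#' empirical comparisons are made).
#'
#' @param model,empirical Aligned richness matrices.
#' @param grid The `grid_spec` giving cell latitudes.
#' @param lat_range Length-2 latitude window in degrees.
#' @return Spearman's rho.
#' @export
spearman_compare <- function(model, empirical, grid,
                             lat_range = c(-54, 71)) {
  stopifnot(all(dim(model) == dim(empirical)))
  latm <- matrix(grid$lat, grid$nlat, grid$nlon)
  sel <- !is.na(model) & !is.na(empirical) &
    latm >= lat_range[1] & latm <= lat_range[2]
  if (sum(sel) < 10) stop("fewer than 10 shared valid cells")
  stats::cor(model[sel], empirical[sel], method = "spearman")
}
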