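test_that("grid specification validates resolution and builds monotone axes", {
  g <- grid_spec(2, 2)
  expect_equal(g$nlon, 180)
  expect_equal(g$nlat, 90)
  expect_true(all(diff(g$lon) > 0))
  expect_true(all(diff(g$lat) < 0))
  expect_error(grid_spec(7, 2), "divide")
  expect_error(grid_spec(90, 90), "degenerate")
})

test_that("generated worlds are deterministic and respect basic structure", {
  cfg <- world_config(seed = 3, n_steps = 8, lon_res = 20, lat_res = 20)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$elevation, w2$elevation)
  expect_identical(w1$land, w2$land)
  w3 <- generate_world(world_config(seed = 4, n_steps = 8, lon_res = 20,
                                    lat_res = 20))
  expect_false(identical(w1$land, w3$land))
  # land fraction strictly inside (0,1) at every step
  lf <- apply(w1$land, 3, mean)
  expect_true(all(lf > 0 & lf < 1))
  # no missing values on land cells
  for (v in c("elevation", "temperature", "precipitation", "discharge"))
    expect_false(anyNA(w1[[v]][w1$land]))
  expect_true(all(w1$precipitation >= 0))
  expect_true(all(w1$discharge[w1$land] >= 0))
})

test_that("zonal-mean temperature is non-increasing in absolute latitude", {
  w <- tiny_world()
  for (ti in seq_along(w$times)) {
    zm <- rowMeans(w$temperature[, , ti])
    lat <- w$grid$lat
    n <- zm[lat > 0][order(lat[lat > 0])]        # equator -> north pole
    s <- zm[lat < 0][order(-lat[lat < 0])]       # equator -> south pole
    expect_true(all(diff(n) <= 1e-9))
    expect_true(all(diff(s) <= 1e-9))
  }
})

test_that("northern land-area excess appears when asymmetry > 0 and vanishes on average when 0", {
  areas_ratio <- function(w) {
    am <- cell_area_matrix(w$grid)
    north <- w$grid$lat > 0
    south <- w$grid$lat < 0   # equator row belongs to neither hemisphere
    sum(am[north, ] * w$land[north, , 1]) /
      sum(am[south, ] * w$land[south, , 1])
  }
  ratios <- vapply(1:8, function(s) {
    cfg <- world_config(seed = s, n_steps = 1, lon_res = 20, lat_res = 20,
                        hemisphere_asymmetry = 0.5)
    areas_ratio(generate_world(cfg))
  }, numeric(1))
  expect_true(all(ratios >= 1))
  # symmetric configuration: signed log-ratio averages toward 0
  lr <- vapply(1:40, function(s) {
    cfg <- world_config(seed = 100 + s, n_steps = 1, lon_res = 20,
                        lat_res = 20, hemisphere_asymmetry = 0)
    log(areas_ratio(generate_world(cfg)))
  }, numeric(1))
  expect_lt(abs(mean(lr)), stats::sd(lr))  # centered near zero
})

test_that("the climate shock drops zonal temperature and precipitation at its onset", {
  cfg <- world_config(seed = 5, n_steps = 12, lon_res = 20, lat_res = 20,
                      kpg_time = 6, kpg_severity = 0.25,
                      sealevel_amplitude = 0, climate_cycle_amplitude = 0)
  w <- generate_world(cfg)
  i_ev <- which(w$times == 6)
  dT <- mean(w$temperature[, , i_ev - 1]) - mean(w$temperature[, , i_ev])
  expect_equal(dT, 0.25 * (cfg$equator_T - cfg$pole_T), tolerance = 1e-8)
  ratP <- mean(w$precipitation[, , i_ev]) / mean(w$precipitation[, , i_ev - 1])
  expect_equal(ratP, 0.75, tolerance = 1e-8)
  # null perturbation: severity 0 reproduces the unshocked series exactly
  cfg0 <- world_config(seed = 5, n_steps = 12, lon_res = 20, lat_res = 20,
                       kpg_time = 6, kpg_severity = 0,
                       sealevel_amplitude = 0, climate_cycle_amplitude = 0)
  cfg_null <- world_config(seed = 5, n_steps = 12, lon_res = 20,
                           lat_res = 20, kpg_time = NULL,
                           sealevel_amplitude = 0,
                           climate_cycle_amplitude = 0)
  expect_identical(generate_world(cfg0)$temperature,
                   generate_world(cfg_null)$temperature)
})

test_that("flow accumulation routes water downhill and conserves volume", {
  # isolated single land cell: discharge = local P * area
  land <- matrix(FALSE, 4, 4); land[2, 2] <- TRUE
  elev <- matrix(0, 4, 4)
  p <- matrix(1, 4, 4)
  a <- matrix(1e9, 4, 4)
  d <- flow_accumulate(elev, p, a, land)
  expect_equal(d[2, 2], 1e9)
  expect_true(all(is.na(d[!land])))

  # two-cell slope: downstream cell collects both fluxes
  land2 <- matrix(FALSE, 4, 4); land2[2, 2:3] <- TRUE
  elev2 <- matrix(0, 4, 4); elev2[2, 2] <- 100
  d2 <- flow_accumulate(elev2, p, a, land2)
  expect_equal(d2[2, 3], 2e9)
  expect_equal(d2[2, 2], 1e9)

  # all-flat landscape: every cell its own sink
  land3 <- matrix(TRUE, 4, 4)
  d3 <- flow_accumulate(matrix(5, 4, 4), p, a, land3)
  expect_true(all(d3 == 1e9))

  # mass conservation on a rough random field: sinks collect all input
  set.seed(1)
  land4 <- matrix(runif(64) < 0.7, 8, 8)
  elev4 <- matrix(runif(64, 0, 1000), 8, 8)
  p4 <- matrix(runif(64, 0.2, 2), 8, 8)
  a4 <- matrix(1e9, 8, 8)
  d4 <- flow_accumulate(elev4, p4, a4, land4)
  # total discharge into sinks equals the total input over land
  nb <- ldgsim:::neighbor_index(list(nlat = 8, nlon = 8))
  z <- ifelse(land4, elev4, -Inf)
  sink <- vapply(which(land4), function(i) {
    nn <- nb[i, ]; nn <- nn[!is.na(nn)]; nn <- nn[land4[nn]]
    length(nn) == 0 || max(z[i] - z[nn]) <= 0
  }, logical(1))
  expect_equal(sum(d4[which(land4)[sink]]),
               sum((p4 * a4)[land4]), tolerance = 1e-9)
})

test_that("CSV-stack landscape I/O round-trips within the stated precision", {
  w <- generate_world(world_config(seed = 9, n_steps = 3, lon_res = 20,
                                   lat_res = 20))
  dir <- file.path(tempdir(), "world_io")
  write_landscape(w, dir)
  w2 <- read_landscape(dir)
  expect_identical(w2$land, w$land)
  expect_identical(w2$times, as.numeric(w$times))
  for (v in c("elevation", "temperature", "precipitation", "discharge")) {
    rel <- abs(w2[[v]] - w[[v]]) / pmax(abs(w[[v]]), 1e-12)
    expect_lt(max(rel, na.rm = TRUE), 1e-5)
  }
  # a missing variable is reported by name
  file.remove(list.files(dir, pattern = "^precipitation", full.names = TRUE))
  expect_error(read_landscape(dir), "precipitation")
  unlink(dir, recursive = TRUE)
})
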