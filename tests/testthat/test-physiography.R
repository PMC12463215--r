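test_that("TPI matches its definition and the brute-force oracle", {
  # constant field -> TPI 0 everywhere
  land <- matrix(TRUE, 6, 6)
  expect_true(all(compute_tpi(matrix(7, 6, 6), land) == 0))

  # single peak: center 1, annulus 0 -> TPI 1
  z <- matrix(0, 6, 6); z[3, 3] <- 1
  expect_equal(compute_tpi(z, land)[3, 3], 1)

  # random fields vs an independent per-cell loop, both annuli, with sea
  set.seed(11)
  for (rep in 1:3) {
    elev <- matrix(rnorm(64, 500, 300), 8, 8)
    msk <- matrix(runif(64) < 0.8, 8, 8)
    for (band in list(c(0, 1), c(1, 3))) {
      got <- compute_tpi(elev, msk, band[1], band[2])
      want <- brute_tpi(elev, msk, band[1], band[2])
      expect_equal(got, want)
    }
  }
})

test_that("TPI standardization has mean 0, sd 100, and flags flat fields", {
  set.seed(2)
  tpi <- matrix(rnorm(100), 10, 10)
  tpi[sample(100, 20)] <- NA
  s <- standardize_tpi(tpi)
  v <- s[!is.na(s)]
  expect_lt(abs(mean(v)), 1e-9)
  expect_equal(stats::sd(v), 100, tolerance = 1e-6)
  expect_false(attr(s, "flat"))

  flat <- standardize_tpi(matrix(3, 4, 4))
  expect_true(all(flat == 0))
  expect_true(attr(flat, "flat"))

  # balanced two-valued field standardizes to +-100 (large n)
  two <- matrix(rep(c(-5, 5), 800), 40, 40)
  s2 <- standardize_tpi(two)
  expect_equal(sort(unique(as.vector(s2))), c(-100, 100), tolerance = 1e-3)
})

test_that("slope is the arctangent of the steepest gradient and is translation invariant", {
  g <- grid_spec(20, 20)
  land <- matrix(TRUE, g$nlat, g$nlon)
  expect_true(all(compute_slope(matrix(0, g$nlat, g$nlon), land, g) == 0))

  # a rise of 100 m over a 100 km span is atan(0.001) ~ 0.0573 deg;
  # build it on two equator-row cells and scale by their true spacing
  z <- matrix(0, g$nlat, g$nlon)
  eq_rows <- which(abs(g$lat) == min(abs(g$lat)))
  r <- eq_rows[1]
  span_km <- gc_distance(g$lon[1], g$lat[r], g$lon[2], g$lat[r])
  z[r, 2] <- 100 * (span_km / 100)      # gradient 100 m per 100 km
  sl <- compute_slope(z, land, g)
  expect_equal(sl[r, 1], atan(0.001) * 180 / pi, tolerance = 1e-6)

  set.seed(3)
  z2 <- matrix(rnorm(g$nlat * g$nlon, 0, 500), g$nlat, g$nlon)
  expect_equal(compute_slope(z2, land, g), compute_slope(z2 + 1234, land, g))
})

test_that("hierarchical slope and water-flux classifications follow the lookup table", {
  expect_equal(as.vector(categorize_slope(0.2)), 3)
  expect_equal(as.vector(categorize_slope(0.03)), 2)   # inclusive lower bound
  expect_equal(as.vector(categorize_slope(0.0)), 1)
  expect_equal(as.vector(categorize_slope(100)), 10)
  expect_equal(as.vector(categorize_flux(10^7.5)), 2)
  expect_equal(as.vector(categorize_flux(0)), 1)
  expect_equal(as.vector(categorize_flux(1e12)), 5)
  expect_error(categorize_flux(-1), "nonnegative")
  # monotone in discharge
  x <- sort(10^runif(100, 4, 12))
  expect_true(all(diff(as.vector(hydro_categories(x))) >= 0))
  # a field spanning 1e5..1e12 uses all five categories
  span <- 10^seq(5, 12, length.out = 50)
  expect_equal(sort(unique(as.vector(hydro_categories(span)))), 1:5)
})

test_that("physiographic diversity spans [0,1] with the expected special cases", {
  land <- matrix(TRUE, 3, 3)
  cons <- matrix(1, 3, 3)
  # all three layers constant -> phi = 0
  expect_true(all(physiographic_diversity(cons, cons, cons, land) == 0))

  # worked case: one layer with two equally frequent of its ten classes,
  # the others constant -> phi = (ln2/ln10 + 0 + 0)/3. Land is a 10-cell
  # meridional strip fully inside the window, so proportions are exact.
  landw <- matrix(FALSE, 10, 3); landw[, 2] <- TRUE
  strip <- function(vals) { m <- matrix(NA_real_, 10, 3); m[, 2] <- vals; m }
  phi_w <- physiographic_diversity(strip(rep(c(1, 2), 5)), strip(rep(1, 10)),
                                   strip(rep(1, 10)), landw, radius = 10)
  expect_equal(phi_w[5, 2], (log(2) / log(10)) / 3, tolerance = 1e-12)

  # exact phi = 1: every layer uniform over all its classes in the window
  phi1 <- physiographic_diversity(strip(1:10), strip(1:10),
                                  strip(rep(1:5, 2)), landw, radius = 10)
  expect_equal(phi1[5, 2], 1, tolerance = 1e-12)

  # bounds on random neighborhoods
  set.seed(4)
  for (rep in 1:3) {
    landr <- matrix(runif(400) < 0.8, 20, 20)
    t_c <- matrix(sample(1:10, 400, TRUE), 20, 20)
    s_c <- matrix(sample(1:10, 400, TRUE), 20, 20)
    f_c <- matrix(sample(1:5, 400, TRUE), 20, 20)
    phi <- physiographic_diversity(t_c, s_c, f_c, landr)
    v <- phi[!is.na(phi)]
    expect_true(all(v >= 0 & v <= 1 + 1e-12))
  }
})

test_that("full physiography layers are consistent on a generated slice", {
  w <- tiny_world()
  p <- physiography_layers(w, 10)
  land <- w$land[, , 10]
  expect_true(all(is.na(p$phi[!land])))
  expect_true(all(p$phi[land] >= 0 & p$phi[land] <= 1, na.rm = TRUE))
  expect_true(all(p$slope_cat[land] %in% 1:10, na.rm = TRUE))
  expect_true(all(p$H[land] %in% 1:5, na.rm = TRUE))
  expect_true(all(p$tpi_cat[land] %in% 1:10, na.rm = TRUE))
  # averaged standardized TPI keeps mean ~ 0
  expect_lt(abs(mean(p$tpi_s[land], na.rm = TRUE)), 15)
})
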