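test_that("Sobol draws match the reference sequence and respect the parameter ranges", {
  # first 8 unscrambled 5-d points of the Joe-Kuo sequence (independent
  # reference: scipy.stats.qmc.Sobol(d=5, scramble=False))
  ref <- matrix(c(
    0, 0, 0, 0, 0,
    0.5, 0.5, 0.5, 0.5, 0.5,
    0.75, 0.25, 0.25, 0.25, 0.75,
    0.25, 0.75, 0.75, 0.75, 0.25,
    0.375, 0.375, 0.625, 0.875, 0.375,
    0.875, 0.875, 0.125, 0.375, 0.875,
    0.625, 0.125, 0.875, 0.625, 0.625,
    0.125, 0.625, 0.375, 0.125, 0.125), ncol = 5, byrow = TRUE)
  expect_equal(sobol_points(8, 5), ref)
  expect_identical(sobol_points(8, 5), sobol_points(8, 5))  # deterministic
  expect_equal(sobol_points(4, 5, skip = 4), ref[5:8, ])

  p <- sample_parameters(100)
  expect_equal(nrow(p), 100)
  expect_true(all(p$tau >= 0.5 & p$tau <= 3))
  expect_true(all(p$omega_t >= 0.05 & p$omega_t <= 0.25))
  expect_true(all(p$omega_p >= 0.05 & p$omega_p <= 0.25))
  expect_true(all(p$shape >= 2 & p$shape <= 3))
  expect_true(all(p$scale >= 100 & p$scale <= 600))
  expect_true(all(p$sigma == 0.005))
})

test_that("scenario table carries the published forcing weights", {
  for (id in c("M0", "M1s", "M1d")) {
    s <- scenario_spec(id)
    expect_equal(c(s$alpha, s$beta, s$gamma), c(0.5, 0.5, 0))
  }
  e <- scenario_spec("M1e")
  expect_equal(c(e$alpha, e$beta, e$gamma), c(0.33, 0.33, 0.33))
  expect_equal(scenario_spec("M1d")$dispersal_mode, "distance+phi")
  expect_equal(scenario_spec("M1s")$speciation_mode, "phi")
  expect_equal(scenario_spec("M0")$Kmax, 1)
})

test_that("dispersal cost doubles across water and M1d penalizes phi contrast", {
  g <- grid_spec(20, 20)
  land <- matrix(TRUE, g$nlat, g$nlon)
  gr <- dispersal_cost_graph(land, g)
  eq <- which(abs(g$lat) == min(abs(g$lat)))[1]
  a <- (1 - 1) * g$nlat + eq          # (row eq, col 1)
  b <- (2 - 1) * g$nlat + eq          # (row eq, col 2)
  d_ab <- gc_distance(g$lon[1], g$lat[eq], g$lon[2], g$lat[eq])
  expect_equal(cost_distances(gr, a, b)[1, 1], d_ab)

  # carve a meridional sea band through column 2: paths a -> c must touch sea
  land2 <- land; land2[, 2] <- FALSE
  gr2 <- dispersal_cost_graph(land2, g)
  cc <- (3 - 1) * g$nlat + eq
  direct_land <- cost_distances(gr, a, cc)[1, 1]
  expect_gte(cost_distances(gr2, a, cc)[1, 1], 2 * d_ab + d_ab)

  # M1d with a constant phi field reproduces the M0 graph exactly
  phi0 <- matrix(0.4, g$nlat, g$nlon)
  gd <- dispersal_cost_graph(land, g, phi = phi0, scenario_spec("M1d"))
  expect_equal(igraph::E(gd)$weight, igraph::E(gr)$weight)
  # and a phi contrast strictly increases land-edge cost
  phi1 <- phi0; phi1[, 2] <- 0.9
  gd2 <- dispersal_cost_graph(land, g, phi = phi1, scenario_spec("M1d"))
  expect_gt(cost_distances(gd2, a, b)[1, 1], d_ab)
})

test_that("kernel draws follow the Weibull tail and median", {
  set.seed(99)
  n <- 1e6
  r <- rweibull(n, shape = 2, scale = 600)
  p_true <- exp(-(1750 / 600)^2)
  p_hat <- mean(r > 1750)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_hat - p_true), 3 * se)
  expect_equal(stats::qweibull(0.5, 2, 600), 600 * log(2)^(1 / 2),
               tolerance = 1e-12)
  expect_equal(stats::median(r), 600 * sqrt(log(2)), tolerance = 2)

  # a draw below the nearest-neighbor cost colonizes nothing
  dm <- matrix(c(500, 800), 1, 2)
  set.seed(1)
  res <- replicate(50, nrow(disperse(dm * 100, c(5, 6), 2, 3)))
  expect_true(all(res == 0))
})

test_that("cluster partition equals brute-force connected components", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(3:60, 1)
    pts <- matrix(runif(2 * n, 0, 3000), n, 2)
    dm <- as.matrix(stats::dist(pts))
    psi <- runif(1, 200, 1500)
    got <- partition_clusters(dm, psi)
    want <- brute_components(dm, psi)
    # same partition up to label names
    expect_equal(outer(got, got, `==`), outer(want, want, `==`))
  }
  # explicit cases
  expect_equal(max(partition_clusters(matrix(0, 1, 1), 100)), 1)
  two_far <- matrix(c(0, 5000, 5000, 0), 2, 2)
  expect_equal(max(partition_clusters(two_far, 600)), 2)
})

test_that("divergence accumulates, heals on secondary contact, and fires at tau", {
  mk <- function() list(cells = 1:2, N = c(0.5, 0.5), clust = NULL,
                        div = matrix(0, 0, 0), resid = numeric(0))
  # continuous isolation: tau = 3 fires at the third isolated step
  sp <- mk()
  fired_at <- NA
  for (step in 1:5) {
    upd <- update_divergence_and_speciate(sp, c(1L, 2L), tau = 3)
    sp <- upd$species
    if (length(upd$offshoots) > 0) { fired_at <- step; break }
  }
  expect_equal(fired_at, 3)

  # tau = 0.5 fires at the first crossing (one step)
  sp <- mk()
  upd <- update_divergence_and_speciate(sp, c(1L, 2L), tau = 0.5)
  expect_length(upd$offshoots, 1)

  # isolation then reunion heals back to zero: no speciation afterwards
  sp <- mk()
  sp <- update_divergence_and_speciate(sp, c(1L, 2L), tau = 3)$species
  expect_equal(sp$div[1, 2], 1)
  sp <- update_divergence_and_speciate(sp, c(1L, 1L), tau = 3)$species
  expect_equal(sp$resid, 0)              # healed 1 -> 0
  upd <- update_divergence_and_speciate(sp, c(1L, 2L), tau = 3)
  expect_equal(upd$species$div[1, 2], 1) # restarted from zero
  expect_length(upd$offshoots, 0)
})

test_that("trait evolution steps toward local conditions without overshoot", {
  expect_equal(evolve_traits(0.1, 0.3, 0), 0.1)      # sigma 0: frozen
  expect_equal(evolve_traits(0.3, 0.3, 0.005), 0.3)  # at optimum: unchanged
  set.seed(5)
  # never overshoots a nearby target
  out <- replicate(2000, evolve_traits(0.1, 0.101, 0.005))
  expect_true(all(out >= 0.1 & out <= 0.101))
  # expected half-normal step size sigma * sqrt(2/pi)
  set.seed(6)
  n <- 1e6
  steps <- abs(rnorm(n, 0, 0.005))
  m_true <- 0.005 * sqrt(2 / pi)
  se <- stats::sd(steps) / sqrt(n)
  expect_lt(abs(mean(steps) - m_true), 3 * se)
  moved <- replicate(5000, evolve_traits(0, 1, 0.005))
  expect_lt(abs(mean(moved) - m_true), 5 * stats::sd(moved) / sqrt(5000))
})

test_that("suitability and carrying capacity evaluate the published formulas", {
  expect_equal(suitability(0.2, 0.5, 0.2, 0.5, 0.8, 0.1, 0.1), 0.8)
  expect_equal(suitability(0.3, 0.5, 0.2, 0.5, 1, 0.1, 0.1), exp(-1))
  k <- suitability(seq(0.2, 0.5, 0.05), 0.5, 0.2, 0.5, 1, 0.1, 0.1)
  expect_true(all(diff(k) < 0))          # strictly decreasing in mismatch

  m0 <- scenario_spec("M0")
  expect_equal(carrying_capacity(1, 1, 0, 0, m0), 1)
  expect_equal(carrying_capacity(1, 1, 0, 60, m0), 0.5)
  expect_equal(carrying_capacity(1, 1, 1, 0, scenario_spec("M1e")),
               min(1, 0.99))
  expect_equal(carrying_capacity(1, 1, 0, 90, m0), 0)
  expect_equal(carrying_capacity(1, 1, 0, 95, m0), 0)
})

test_that("logistic growth fixes N = K, steps as printed, prunes the unviable, and converges", {
  expect_equal(population_step(0.5, 0.5), 0.5)
  expect_equal(population_step(0.2, 0.5), 0.26)
  expect_equal(population_step(0.009, 0.005), 0)   # below viability
  # monotone convergence to K from any N0 in (0, K]
  for (K in c(0.05, 0.3, 0.7, 1)) {
    for (N0 in c(0.011, K / 2, K)) {
      N <- N0
      prev <- N
      for (i in 1:600) {
        N <- population_step(N, K, prune = FALSE)
        expect_gte(N + 1e-12, prev)
        expect_lte(N, K + 1e-12)
        prev <- N
      }
      expect_equal(N, K, tolerance = 1e-6)
    }
  }
})

test_that("reapportionment splits the site total by suitability and conserves it", {
  expect_equal(reapportion(0.7, Ks = 0.6), 0.6)             # single species
  expect_equal(reapportion(c(0.4, 0.4), 0.6), c(0.3, 0.3))  # symmetry
  set.seed(8)
  for (rep in 1:50) {
    K <- runif(sample(1:6, 1), 0, 1)
    Ks <- runif(1, 0.05, 1)
    sh <- reapportion(K, Ks)
    if (any(sh > 0)) expect_equal(sum(sh), Ks, tolerance = 1e-12)
    expect_true(all(sh == 0 | sh >= 0.01))
  }
  expect_equal(reapportion(c(0, 0), 0.5), c(0, 0))   # all unsuitable
  expect_equal(reapportion(c(1, 1), 0.015), c(0.015, 0))  # weakest dropped
})

test_that("a full simulation keeps its bookkeeping and richness invariants", {
  r <- tiny_record()
  n_t <- length(r$times)
  expect_equal(n_t, 31)    # full span executed
  # S(t+1) = S(t) + originations - extinctions, via the rates() audit
  expect_no_error(rates(r))
  # abundances cleaned to [0.01, 1] is implicit; richness is integer >= 0
  expect_true(all(r$richness >= 0))
  # phylogeny tips = total species; extinct + extant partition ids
  expect_equal(sum(is.na(r$species$extinct_age)) +
                 sum(!is.na(r$species$extinct_age)), nrow(r$species))
  # determinism: same seed bit-identical, different seed diverges eventually
  w <- tiny_world()
  d <- sample_parameters(1, skip = 1)
  r2 <- run_simulation(w, scenario_spec("M1e"), d[1, ], seed = 7, spinup = 5)
  expect_identical(r$richness, r2$richness)
  expect_identical(r$events, r2$events)
})

test_that("a single habitable refuge with no isolation keeps exactly one species", {
  g <- grid_spec(20, 20)
  dims <- c(g$nlat, g$nlon, 6)
  land <- array(FALSE, dims); land[5, 3, ] <- TRUE
  elev <- array(NA_real_, dims); elev[5, 3, ] <- 100
  temp <- array(10, dims)
  prec <- array(1, dims)
  disc <- array(NA_real_, dims); disc[5, 3, ] <- 1e9
  series <- structure(list(grid = g, times = 5:0, config = NULL,
                           elevation = elev, temperature = temp,
                           precipitation = prec, discharge = disc,
                           land = land), class = "landscape_series")
  d <- sample_parameters(1, skip = 1)
  r <- run_simulation(series, scenario_spec("M0"), d[1, ], seed = 1,
                      spinup = 0)
  expect_equal(nrow(r$species), 1)
  expect_true(all(apply(r$richness, 3, sum) == 1))
})

test_that("phi cannot leak into scenarios that do not use it", {
  w <- tiny_world()
  sc <- scenario_spec("M0")
  phys <- physiography_layers(w, 10)
  sl1 <- ldgsim:::prepare_slice(w, 10, sc, phys = phys)
  phys_perm <- phys
  land <- w$land[, , 10]
  set.seed(77)
  phys_perm$phi[land] <- sample(phys$phi[land])
  sl2 <- ldgsim:::prepare_slice(w, 10, sc, phys = phys_perm)
  expect_identical(sl1$Ks, sl2$Ks)
  expect_identical(sl1$D, sl2$D)
  expect_null(sl1$D_barrier)
})

test_that("phylogenies round-trip through newick with correct tips and depths", {
  # constructed record: one speciation at 100 Ma in a 150 Ma run
  rec <- list(species = data.frame(id = c(1L, 2L), parent = c(NA, 1L),
                                   origin_age = c(150, 100),
                                   extinct_age = c(NA, NA)),
              times = 150:0)
  nwk <- write_phylogeny(rec)
  tr <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(max(ape::node.depth.edgelength(tr)), 100)

  # single species: one tip spanning the whole run
  rec1 <- list(species = data.frame(id = 1L, parent = NA_integer_,
                                    origin_age = 150, extinct_age = NA),
               times = 150:0)
  tr1 <- ape::read.tree(text = write_phylogeny(rec1))
  expect_equal(ape::Ntip(tr1), 1)

  # a simulated record: tip count = originations + 1, times round-trip
  r <- tiny_record()
  tr2 <- ape::read.tree(text = write_phylogeny(r))
  expect_equal(ape::Ntip(tr2),
               sum(r$events$type == "origination") + 1)
  expect_true(all(tr2$edge.length >= 0))
})
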