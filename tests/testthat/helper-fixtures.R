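# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tiny_world <- function(seed = 42, n_steps = 30) {
  cached(sprintf("tiny_%d_%d", seed, n_steps),
         make_fixtures("tiny", seed = seed, n_steps = n_steps)$world)
}

# Small record for metric tests: tiny world, mid-range parameter draw.
tiny_record <- function(scenario = "M1e", seed = 7) {
  cached(sprintf("rec_%s_%d", scenario, seed), {
    w <- tiny_world()
    d <- sample_parameters(1, skip = 1)
    run_simulation(w, scenario_spec(scenario), d[1, ], seed = seed,
                   spinup = 5)
  })
}

# The frozen 20-replicate study used by the stochastic acceptance checks:
# replicate s = tiny world seed s (60 steps), Sobol draw s, sim seed 1000+s.
acceptance_ensemble <- function() {
  cached("acc_ensemble", {
    d <- sample_parameters(20, skip = 1)
    lapply(1:20, function(s) {
      w <- make_fixtures("tiny", seed = s, n_steps = 60)$world
      run_simulation(w, scenario_spec("M1e"), d[s, ], seed = 1000 + s)
    })
  })
}

# Brute-force oracles (independent of the package implementations).

brute_tpi <- function(elev, land, inner, outer) {
  nlat <- nrow(elev); nlon <- ncol(elev)
  out <- matrix(NA_real_, nlat, nlon)
  for (r in 1:nlat) for (c in 1:nlon) {
    if (!land[r, c]) next
    vals <- c()
    for (dr in -outer:outer) for (dc in -outer:outer) {
      d <- max(abs(dr), abs(dc))
      if (d <= inner || d > outer) next
      rr <- r + dr
      cc <- ((c - 1 + dc) %% nlon) + 1
      if (rr < 1 || rr > nlat) next
      if (land[rr, cc]) vals <- c(vals, elev[rr, cc])
    }
    if (length(vals) > 0) out[r, c] <- elev[r, c] - mean(vals)
  }
  out
}

brute_components <- function(dist_mat, psi) {
  n <- nrow(dist_mat)
  lab <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (lab[v] != 0) next
      lab[v] <- cur
      nb <- which(dist_mat[v, ] <= psi & lab == 0)
      stack <- c(stack, nb)
    }
  }
  lab
}
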