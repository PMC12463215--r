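#' Scenario specification
#'
#' The four eco-evolutionary forcing scenarios. All share distance-based
#' dispersal cost and distance-based isolation except: `M1d` adds a
#' physiographic dissimilarity penalty to dispersal cost, `M1s` severs
#' isolation-clustering paths through high-physiography barrier cells, and
#' `M1e` adds physiographic diversity to the carrying-capacity resource mix
#' (weights 0.33/0.33/0.33 instead of 0.5/0.5/0).
#'
#' @param id One of "M0", "M1s", "M1d", "M1e".
#' @param barrier_quantile Land-cell phi quantile above which cells act as
#'   barriers in `M1s` (default 0.75).
#' @return List of class `scenario_spec` with fields `id`, `dispersal_mode`,
#'   `speciation_mode`, resource weights `alpha`, `beta`, `gamma`, and `Kmax`.
#' @export
scenario_spec <- function(id = c("M0", "M1s", "M1d", "M1e"),
                          barrier_quantile = 0.75) {
  id <- match.arg(id)
  w <- if (id == "M1e") c(0.33, 0.33, 0.33) else c(0.5, 0.5, 0)
  structure(list(
    id = id,
    dispersal_mode = if (id == "M1d") "distance+phi" else "distance",
    speciation_mode = if (id == "M1s") "phi" else "distance",
    alpha = w[1], beta = w[2], gamma = w[3],
    Kmax = 1, barrier_quantile = barrier_quantile
  ), class = "scenario_spec")
}

#' Dispersal cost graph of a landscape slice
#'
#' Weighted 8-neighbor graph over all grid cells. Land-land edges cost the
#' great-circle distance between cell centers (km); any edge touching a sea
#' cell costs twice the distance (crossing water doubles the cost). Under
#' scenario `M1d` land-land edges are further multiplied by
#' `1 + |phi_a - phi_b|`, making environmentally dissimilar sites harder to
#' reach. Pairwise dispersal cost is the shortest path on this graph.
#'
#' @param land Logical land-mask matrix.
#' @param grid The `grid_spec`.
#' @param phi Physiographic diversity matrix (required for `M1d`).
#' @param scenario A [scenario_spec()].
#' @return An igraph graph whose vertices are grid cells (column-major linear
#'   index order) with edge attribute `weight` in cost-km.
#' @export
dispersal_cost_graph <- function(land, grid, phi = NULL,
                                 scenario = scenario_spec("M0")) {
  nlat <- grid$nlat; nlon <- grid$nlon
  ncell <- nlat * nlon
  latv <- rep(grid$lat, times = nlon)
  lonv <- rep(grid$lon, each = nlat)
  nb <- neighbor_index(grid)
  # half the offsets to avoid duplicate undirected edges: E, SW, S, SE
  half <- which(NEIGH8[, "dc"] == 1 | (NEIGH8[, "dc"] == 0 & NEIGH8[, "dr"] == 1))
  from <- integer(0); to <- integer(0)
  for (k in half) {
    j <- nb[, k]
    ok <- !is.na(j)
    from <- c(from, which(ok)); to <- c(to, j[ok])
  }
  w <- gc_distance(lonv[from], latv[from], lonv[to], latv[to])
  landv <- as.vector(land)
  sea_touch <- !landv[from] | !landv[to]
  w[sea_touch] <- 2 * w[sea_touch]
  if (scenario$dispersal_mode == "distance+phi") {
    if (is.null(phi)) stop("scenario M1d requires a phi layer")
    phiv <- as.vector(phi)
    both_land <- !sea_touch
    dphi <- abs(phiv[from] - phiv[to])
    dphi[is.na(dphi)] <- 0
    w[both_land] <- w[both_land] * (1 + dphi[both_land])
  }
  g <- igraph::make_empty_graph(n = ncell, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  g
}

#' Pairwise cost distances between cells
#'
#' Shortest-path distances on a dispersal cost graph.
#'
#' @param graph Graph from [dispersal_cost_graph()].
#' @param from,to Linear cell indices.
#' @return Matrix of cost distances (km); `Inf` where unreachable.
#' @export
cost_distances <- function(graph, from, to = from) {
  igraph::distances(graph, v = from, to = to,
                    weights = igraph::E(graph)$weight)
}

#' One dispersal round for a set of occupied cells
#'
#' Each occupied cell makes one Weibull kernel draw `r` (shape `shape`, scale
#' `scale`, km); every target cell within cost distance `r` becomes a
#' candidate colonization from that source. Candidates only — establishment
#' is decided later by reapportionment (a colonizer must end up with
#' abundance >= 0.01).
#'
#' @param dist_mat Cost distances, occupied cells x target cells (km).
#' @param target_cells Linear indices labelling the columns of `dist_mat`.
#' @param shape,scale Weibull kernel parameters (scale in km).
#' @return Data frame with columns `cell` (colonized target) and `source_row`
#'   (row index of the reaching source; nearest reaching source on ties).
#' @export
disperse <- function(dist_mat, target_cells, shape, scale) {
  n_occ <- nrow(dist_mat)
  if (n_occ == 0 || length(target_cells) == 0)
    return(data.frame(cell = integer(0), source_row = integer(0)))
  r <- stats::rweibull(n_occ, shape = shape, scale = scale)
  reach <- dist_mat <= r            # recycles r down columns? no: by row
  reach <- dist_mat <= matrix(r, n_occ, ncol(dist_mat))
  hit <- which(colSums(reach) > 0)
  if (length(hit) == 0)
    return(data.frame(cell = integer(0), source_row = integer(0)))
  src <- vapply(hit, function(j) {
    rows <- which(reach[, j])
    rows[which.min(dist_mat[rows, j])]
  }, integer(1))
  data.frame(cell = target_cells[hit], source_row = src)
}

#' Partition occupied cells into isolation clusters
#'
#' Clusters are the connected components of the graph linking two occupied
#' cells whenever their pairwise cost distance is at most `psi` (the kernel
#' scale, used as the reachability proxy for gene flow).
#'
#' @param dist_mat Square cost-distance matrix among the occupied cells.
#' @param psi Reachability radius (km).
#' @return Integer vector of cluster labels (1-based, order of appearance).
#' @export
partition_clusters <- function(dist_mat, psi) {
  n <- nrow(dist_mat)
  if (n == 0) return(integer(0))
  adj <- (dist_mat <= psi)
  adj[is.na(adj)] <- FALSE
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  as.integer(match(comp, unique(comp)))
}

#' Update the divergence ledger and detect speciation
#'
#' Divergence between every pair of current clusters grows by 1 per step of
#' isolation; clusters re-united into one heal by 1 per step (floored at 0,
#' carried as a within-cluster residual that re-splitting clusters inherit).
#' A cluster whose divergence from every other cluster has reached `tau`
#' splits off as a new species; the cluster holding the largest total
#' abundance always remains the parent.
#'
#' @param species Internal species state (fields `cells`, `N`, `clust`
#'   old labels, `div` old ledger, `resid` old residuals).
#' @param partition New cluster labels, one per occupied cell.
#' @param tau Divergence threshold.
#' @return List with the updated `species` (new ledger, labels, residuals)
#'   and `offshoots`, a list of row-index vectors (cells of each cluster that
#'   must become a new species).
#' @export
update_divergence_and_speciate <- function(species, partition, tau) {
  k <- max(partition)
  olds <- species$clust      # may be NULL on the first step
  div_old <- species$div
  resid_old <- species$resid
  div <- matrix(0, k, k)
  resid <- numeric(k)
  if (!is.null(olds) && !is.null(div_old) && nrow(div_old) > 0) {
    memb <- lapply(seq_len(k), function(a) unique(olds[partition == a &
                                                         !is.na(olds)]))
    for (a in seq_len(k)) {
      oa <- memb[[a]]
      if (length(oa) > 1) {
        resid[a] <- max(div_old[oa, oa])
      }
      if (length(oa) >= 1) resid[a] <- max(resid[a], resid_old[oa])
    }
    if (k > 1) {
      for (a in seq_len(k - 1)) for (b in (a + 1):k) {
        oa <- memb[[a]]; ob <- memb[[b]]
        shared <- intersect(oa, ob)
        d <- 0
        if (length(oa) && length(ob)) {
          cross <- div_old[oa, ob, drop = FALSE]
          only <- outer(oa, ob, `==`)
          cross[only] <- 0     # same old cluster contributes via residual
          d <- max(0, cross)
          if (length(shared)) d <- max(d, resid_old[shared])
        }
        div[a, b] <- div[b, a] <- d
      }
    }
  }
  if (k > 1) {
    div <- div + 1
    diag(div) <- 0
  }
  resid <- pmax(0, resid - 1)

  offshoots <- list()
  if (k > 1) {
    tot_n <- vapply(seq_len(k), function(a) sum(species$N[partition == a]),
                    numeric(1))
    main <- which.max(tot_n)
    for (a in seq_len(k)) {
      if (a == main) next
      if (min(div[a, -a]) >= tau)
        offshoots <- c(offshoots, list(which(partition == a)))
    }
  }
  species$clust <- partition
  species$div <- div
  species$resid <- resid
  list(species = species, offshoots = offshoots)
}

#' Directed stochastic trait evolution
#'
#' One evolutionary step of the thermal optimum: a half-normal increment
#' `|N(0, sigma^2)|` moves the optimum toward the local mean temperature,
#' never overshooting it. With the temperature normalization of 100 deg C per
#' unit, sigma = 0.005 corresponds to steps of at most 0.5 deg C scale
#' (expected step `sigma * sqrt(2/pi)` ~ 0.4 deg C).
#'
#' @param t_opt Current optima (normalized units; vectorized over clusters).
#' @param t_local Local mean temperatures the optima are drawn toward.
#' @param sigma Standard deviation of the underlying normal (0 = no change).
#' @return Updated optima.
#' @export
evolve_traits <- function(t_opt, t_local, sigma) {
  if (length(t_opt) == 0) return(t_opt)
  step <- abs(stats::rnorm(length(t_opt), 0, sigma))
  gap <- t_local - t_opt
  t_opt + sign(gap) * pmin(step, abs(gap))
}

#' Environmental suitability (Gaussian niche match)
#'
#' `K = Ks * exp(-((Ti-Ts)/omega_t)^2) * exp(-((Pi-Ps)/omega_p)^2)`: the
#' local growth potential declines Gaussian-wise with the mismatch between a
#' species' thermal/precipitation optima and local conditions, scaled by the
#' cell carrying capacity.
#'
#' @param t_opt,p_opt Species optima (normalized units).
#' @param t_s,p_s Local conditions (normalized units).
#' @param Ks Cell carrying capacity.
#' @param omega_t,omega_p Niche widths (> 0).
#' @return Suitability K (same shape as inputs).
#' @export
suitability <- function(t_opt, p_opt, t_s, p_s, Ks, omega_t, omega_p) {
  stopifnot(omega_t > 0, omega_p > 0)
  Ks * exp(-((t_opt - t_s) / omega_t)^2) * exp(-((p_opt - p_s) / omega_p)^2)
}

#' Cell carrying capacity
#'
#' `Ks = min(Kmax, (alpha*P + beta*H + gamma*Phi) * Kmax) * cos(lat)`, with
#' all three resources normalized to [0,1] over the slice and `Kmax = 1`.
#' The cosine factor accounts for the latitudinal shrinkage of cell area;
#' cells at or beyond +-90 deg have capacity 0.
#'
#' @param P_bar,H_bar,Phi_bar Normalized resources in [0,1] (vectorized).
#' @param lat Latitude in degrees.
#' @param scenario A [scenario_spec()] supplying the weights.
#' @return Carrying capacity in [0, Kmax].
#' @export
carrying_capacity <- function(P_bar, H_bar, Phi_bar, lat, scenario) {
  k <- pmin(scenario$Kmax,
            (scenario$alpha * P_bar + scenario$beta * H_bar +
               scenario$gamma * Phi_bar) * scenario$Kmax)
  cl <- cos(lat * pi / 180)
  cl[abs(lat) >= 90] <- 0
  pmax(0, k * cl)
}

#' Logistic population update
#'
#' `N' = N + N * (K - N)`; populations falling below the 0.01 viability
#' threshold are removed (set to 0) when `prune = TRUE`. N = K is a fixed
#' point and for starting values in (0, K] with K <= 1 the map converges
#' monotonically to K.
#'
#' @param N Current abundances.
#' @param K Growth potentials (suitabilities).
#' @param prune Remove populations below 0.01 (default TRUE).
#' @return Updated abundances.
#' @export
population_step <- function(N, K, prune = TRUE) {
  n2 <- N + N * (K - N)
  if (prune) n2[n2 < 0.01] <- 0
  n2
}

#' Reapportion site abundance by suitability
#'
#' Triggered on colonization or local extinction in a site: the site total is
#' reset to the carrying capacity `Ks` and split across the species present
#' proportionally to their suitabilities `K`. Species whose share would fall
#' below 0.01 are not established (removed), and the remainder is re-split
#' until stable; when every species fails, the site is emptied.
#'
#' @param K Suitabilities of the species present at the site.
#' @param Ks Site carrying capacity.
#' @return Vector of abundances (zeros for non-established species); sums to
#'   `Ks` whenever at least one species establishes.
#' @export
reapportion <- function(K, Ks) {
  share <- numeric(length(K))
  active <- which(K > 0)
  repeat {
    if (length(active) == 0) return(share)
    s <- Ks * K[active] / sum(K[active])
    bad <- s < 0.01
    if (!any(bad)) {
      share[active] <- s
      return(share)
    }
    # drop the single weakest (latest index on ties) and re-split
    worst <- which(s == min(s))
    active <- active[-worst[length(worst)]]
  }
}

# --- full simulation -------------------------------------------------------

# Per-slice environment used by the engine. P_ref is the series-wide maximum
# precipitation (the niche normalization constant); carrying-capacity inputs
# are normalized by their slice maxima.
prepare_slice <- function(series, ti, scenario, phys = NULL, P_ref = NULL) {
  grid <- series$grid
  land <- series$land[, , ti]
  if (is.null(phys)) phys <- physiography_layers(series, ti)
  latm <- matrix(grid$lat, grid$nlat, grid$nlon)
  Pn_slice <- series$precipitation[, , ti]
  P_bar <- Pn_slice / max(Pn_slice[land], na.rm = TRUE)
  if (is.null(P_ref)) P_ref <- max(Pn_slice[land], na.rm = TRUE)
  H_bar <- phys$H / 5
  phi <- phys$phi
  phi_max <- suppressWarnings(max(phi[land], na.rm = TRUE))
  Phi_bar <- if (is.finite(phi_max) && phi_max > 0) phi / phi_max else phi * 0
  Phi_bar[land & is.na(Phi_bar)] <- 0
  Ks <- matrix(0, grid$nlat, grid$nlon)
  Ks[land] <- carrying_capacity(P_bar[land], H_bar[land], Phi_bar[land],
                                latm[land], scenario)
  Ks[is.na(Ks)] <- 0
  g <- dispersal_cost_graph(land, grid, phi = phi, scenario = scenario)
  land_cells <- which(land)
  D <- cost_distances(g, land_cells)
  D_barrier <- NULL
  if (scenario$speciation_mode == "phi") {
    # high-phi cells block transit: paths may start or end on a barrier
    # cell (via its direct edges) but never pass through one
    thr <- stats::quantile(phi[land], scenario$barrier_quantile, na.rm = TRUE)
    barrier <- land_cells[!is.na(phi[land_cells]) & phi[land_cells] > thr]
    keep <- setdiff(land_cells, barrier)
    n_land <- length(land_cells)
    pos <- match(seq_len(grid$nlat * grid$nlon), land_cells)  # cell -> row
    Db <- matrix(Inf, n_land, n_land)
    if (length(keep) > 1) {
      g2 <- igraph::delete_vertices(g, barrier)
      remain <- setdiff(seq_len(grid$nlat * grid$nlon), barrier)
      Dk <- igraph::distances(g2, v = match(keep, remain),
                              to = match(keep, remain),
                              weights = igraph::E(g2)$weight)
      kp <- pos[keep]
      Db[kp, kp] <- Dk
      # one-step relaxation for barrier endpoints
      nb <- neighbor_index(grid)
      latv <- rep(grid$lat, times = grid$nlon)
      lonv <- rep(grid$lon, each = grid$nlat)
      edge_w <- function(a, b) {
        w <- gc_distance(lonv[a], latv[a], lonv[b], latv[b])
        if (!land[a] || !land[b]) w <- 2 * w
        w
      }
      b_nb <- lapply(barrier, function(a) {
        nn <- nb[a, ]; nn <- nn[!is.na(nn)]
        u <- nn[nn %in% keep]
        if (length(u) == 0) return(NULL)
        list(u = pos[u], w = vapply(u, function(x) edge_w(a, x), numeric(1)))
      })
      for (ai in seq_along(barrier)) {
        bn <- b_nb[[ai]]
        if (is.null(bn)) next
        rowv <- do.call(pmin, lapply(seq_along(bn$u), function(k)
          bn$w[k] + Db[bn$u[k], ]))
        Db[pos[barrier[ai]], ] <- pmin(Db[pos[barrier[ai]], ], rowv)
        Db[, pos[barrier[ai]]] <- pmin(Db[, pos[barrier[ai]]], rowv)
      }
      # barrier-barrier rows: min over each endpoint's neighbor gateways
      for (ai in seq_along(barrier)) {
        bn <- b_nb[[ai]]
        if (is.null(bn)) next
        for (bi in seq_along(barrier)) {
          if (bi == ai) next
          cn <- b_nb[[bi]]
          if (is.null(cn)) next
          val <- min(outer(bn$w, cn$w, `+`) + Db[bn$u, cn$u])
          r_a <- pos[barrier[ai]]; r_b <- pos[barrier[bi]]
          if (val < Db[r_a, r_b]) Db[r_a, r_b] <- Db[r_b, r_a] <- val
        }
      }
      # direct edges between adjacent cells always usable
      for (a in land_cells) {
        nn <- nb[a, ]; nn <- nn[!is.na(nn)]
        nn <- nn[nn %in% land_cells]
        for (b in nn) {
          w <- edge_w(a, b)
          r_a <- pos[a]; r_b <- pos[b]
          if (w < Db[r_a, r_b]) Db[r_a, r_b] <- Db[r_b, r_a] <- w
        }
      }
    }
    diag(Db) <- 0
    D_barrier <- Db
  }
  # normalized climate for niches (temperature: 100 deg C per unit)
  Tn <- series$temperature[, , ti] / 100
  Pn <- Pn_slice / P_ref
  list(land = land, land_cells = land_cells, Ks = Ks, D = D,
       D_barrier = D_barrier, Tn = Tn, Pn = Pn, P_bar = P_bar, phi = phi,
       latm = latm)
}

#' Run one forward eco-evolutionary simulation
#'
#' Starts one ancestral species on the largest landmass (habitable cell
#' nearest the equator) and iterates, per 1-Myr step: landscape update,
#' dispersal (one Weibull kernel draw per occupied cell against shortest-path
#' cost distances), isolation clustering (reachability radius = kernel
#' scale), divergence accumulation and allopatric speciation at threshold
#' `tau`, directed half-normal thermal-niche evolution, and ecology
#' (Gaussian suitability, resource-weighted carrying capacity, logistic
#' growth, reapportionment on colonization/local extinction, removal below
#' abundance 0.01). A species with no occupied site left goes globally
#' extinct. The run is deterministic for a fixed seed.
#'
#' On grids coarser than the 2-degree reference, kernel scale and
#' reachability radius are multiplied by `lon_res / 2` so that dispersal
#' reach relative to cell spacing is preserved.
#'
#' @param series A `landscape_series`.
#' @param scenario A [scenario_spec()].
#' @param draw One row of [sample_parameters()] (fields `tau`, `omega_t`,
#'   `omega_p`, `shape`, `scale`, `sigma`).
#' @param seed Integer seed for the simulation's RNG stream.
#' @param init Optional linear cell index for the ancestral species
#'   (must be land at the first slice).
#' @param spinup Steps excluded from analysis summaries (default 25).
#' @return A `simulation_record`: `richness` array (nlat x nlon x n_times),
#'   `events` data frame (step, age, type, species, parent, n_cells),
#'   `event_cells` list of cell-index vectors per event, `species` table
#'   (id, parent, origin_age, extinct_age), `land` mask array, `grid`,
#'   `times`, `spinup`, `scenario_id`, `draw`.
#' @export
run_simulation <- function(series, scenario, draw, seed = 1, init = NULL,
                           spinup = 25) {
  grid <- series$grid
  n_t <- length(series$times)
  res_factor <- grid$lon_res / 2
  psi_eff <- draw$scale * res_factor

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  P_ref <- max(series$precipitation[series$land], na.rm = TRUE)

  richness <- array(0L, c(grid$nlat, grid$nlon, n_t))
  events <- list()
  event_cells <- list()
  sp_tab <- list()

  slice <- prepare_slice(series, 1, scenario, P_ref = P_ref)
  # ancestral placement: largest landmass, habitable cell nearest the equator
  if (is.null(init)) {
    g_land <- igraph::graph_from_adjacency_matrix(
      slice$D < Inf, mode = "undirected")
    comp <- igraph::components(g_land)$membership
    big <- which(comp == which.max(tabulate(comp)))
    cand <- slice$land_cells[big]
    cand <- cand[slice$Ks[cand] >= 0.01]
    if (length(cand) == 0) stop("no habitable cell for initialization")
    init <- cand[which.min(abs(slice$latm[cand]))]
  } else {
    if (!slice$land[init]) stop("ancestral placement on a sea cell")
  }
  next_id <- 2L
  spp <- list(list(
    id = 1L, parent = NA_integer_, origin_age = series$times[1],
    extinct_age = NA_real_,
    cells = init, N = max(0.01, slice$Ks[init]),
    Topt = slice$Tn[init], Popt = slice$Pn[init],
    clust = NULL, div = matrix(0, 0, 0), resid = numeric(0),
    last_cells = init))
  richness[, , 1][init] <- 1L

  for (ti in 2:n_t) {
    slice <- prepare_slice(series, ti, scenario, P_ref = P_ref)
    pos_of_cell <- rep(NA_integer_, grid$nlat * grid$nlon)
    pos_of_cell[slice$land_cells] <- seq_along(slice$land_cells)
    age <- series$times[ti]
    extinct_now <- integer(0)

    # landscape update: drop populations on cells that left the habitable set
    for (si in seq_along(spp)) {
      sp <- spp[[si]]
      if (!is.na(sp$extinct_age)) next
      keep <- slice$land[sp$cells] & slice$Ks[sp$cells] > 0
      if (!all(keep)) spp[[si]] <- sp <- drop_cells(sp, which(!keep))
      if (length(sp$cells) == 0) extinct_now <- c(extinct_now, si)
    }

    # dispersal: candidate colonizations per species
    colonizers <- vector("list", length(spp))
    for (si in seq_along(spp)) {
      sp <- spp[[si]]
      if (!is.na(sp$extinct_age) || length(sp$cells) == 0) next
      occ_pos <- pos_of_cell[sp$cells]
      tgt <- setdiff(slice$land_cells, sp$cells)
      if (length(tgt) == 0) next
      dm <- slice$D[occ_pos, pos_of_cell[tgt], drop = FALSE]
      col <- disperse(dm, tgt, draw$shape, draw$scale * res_factor)
      if (nrow(col) > 0) colonizers[[si]] <- col
    }

    # attach colonizers provisionally (they inherit the source cell's traits
    # and cluster lineage; establishment decided by reapportionment below)
    for (si in seq_along(spp)) {
      col <- colonizers[[si]]
      if (is.null(col)) next
      sp <- spp[[si]]
      src <- col$source_row
      sp$cells <- c(sp$cells, col$cell)
      sp$N <- c(sp$N, rep(0, nrow(col)))      # no abundance until reapportion
      sp$Topt <- c(sp$Topt, sp$Topt[src])
      sp$Popt <- c(sp$Popt, sp$Popt[src])
      if (!is.null(sp$clust)) sp$clust <- c(sp$clust, sp$clust[src])
      sp$colonized <- c(rep(FALSE, length(sp$cells) - nrow(col)),
                        rep(TRUE, nrow(col)))
      spp[[si]] <- sp
    }

    # clustering, divergence, speciation
    n_before <- length(spp)
    for (si in seq_len(n_before)) {
      sp <- spp[[si]]
      if (!is.na(sp$extinct_age) || length(sp$cells) == 0) next
      Dm <- if (scenario$speciation_mode == "phi") slice$D_barrier else slice$D
      occ_pos <- pos_of_cell[sp$cells]
      part <- partition_clusters(Dm[occ_pos, occ_pos, drop = FALSE], psi_eff)
      upd <- update_divergence_and_speciate(sp, part, draw$tau)
      sp <- upd$species
      for (rows in upd$offshoots) {   # rows index the pre-drop occupancy
        newsp <- list(
          id = next_id, parent = sp$id, origin_age = age,
          extinct_age = NA_real_,
          cells = sp$cells[rows], N = sp$N[rows],
          Topt = sp$Topt[rows], Popt = sp$Popt[rows],
          clust = rep(1L, length(rows)), div = matrix(0, 1, 1),
          resid = 0, last_cells = sp$cells[rows],
          colonized = if (is.null(sp$colonized)) NULL else sp$colonized[rows])
        events[[length(events) + 1]] <- data.frame(
          step = ti, age = age, type = "origination", species = next_id,
          parent = sp$id, n_cells = length(rows))
        event_cells[[length(event_cells) + 1]] <- newsp$cells
        next_id <- next_id + 1L
        spp[[length(spp) + 1]] <- newsp
      }
      if (length(upd$offshoots) > 0)
        sp <- drop_cells(sp, unlist(upd$offshoots), relabel = TRUE)
      spp[[si]] <- sp
    }

    # trait evolution: per cluster, toward cluster-local mean temperature
    for (si in seq_along(spp)) {
      sp <- spp[[si]]
      if (!is.na(sp$extinct_age) || length(sp$cells) == 0) next
      for (cl in unique(sp$clust)) {
        rows <- which(sp$clust == cl)
        t_local <- mean(slice$Tn[sp$cells[rows]])
        t_now <- mean(sp$Topt[rows])
        sp$Topt[rows] <- evolve_traits(t_now, t_local, draw$sigma)
      }
      spp[[si]] <- sp
    }

    # ecology: suitability, growth, reapportionment
    alive <- which(vapply(spp, function(s)
      is.na(s$extinct_age) && length(s$cells) > 0, logical(1)))
    if (length(alive) > 0) {
      occ_si <- integer(0); occ_row <- integer(0); occ_cell <- integer(0)
      occ_N <- numeric(0); occ_K <- numeric(0); occ_new <- logical(0)
      for (si in alive) {
        sp <- spp[[si]]
        K <- suitability(sp$Topt, sp$Popt, slice$Tn[sp$cells],
                         slice$Pn[sp$cells], slice$Ks[sp$cells],
                         draw$omega_t, draw$omega_p)
        nn <- length(sp$cells)
        occ_si <- c(occ_si, rep(si, nn))
        occ_row <- c(occ_row, seq_len(nn))
        occ_cell <- c(occ_cell, sp$cells)
        occ_N <- c(occ_N, sp$N)
        occ_K <- c(occ_K, K)
        occ_new <- c(occ_new, if (is.null(sp$colonized))
          rep(FALSE, nn) else sp$colonized)
      }
      newN <- occ_N
      for (cell in unique(occ_cell)) {
        at <- which(occ_cell == cell)
        if (any(occ_new[at])) {
          newN[at] <- reapportion(occ_K[at], slice$Ks[cell])
        } else {
          n2 <- population_step(occ_N[at], occ_K[at])
          if (any(n2 == 0) && any(n2 > 0)) {
            surv <- n2 > 0
            n2[surv] <- reapportion(ifelse(surv, occ_K[at], 0),
                                    slice$Ks[cell])[surv]
          }
          newN[at] <- n2
        }
      }
      for (si in alive) {
        rows <- which(occ_si == si)
        sp <- spp[[si]]
        sp$N <- newN[rows][order(occ_row[rows])]
        sp$colonized <- NULL
        dead <- which(sp$N < 0.01)
        if (length(dead) > 0) sp <- drop_cells(sp, dead, relabel = TRUE)
        if (length(sp$cells) == 0) extinct_now <- c(extinct_now, si)
        spp[[si]] <- sp
      }
    }

    # global extinctions
    for (si in unique(extinct_now)) {
      sp <- spp[[si]]
      if (!is.na(sp$extinct_age)) next
      sp$extinct_age <- age
      events[[length(events) + 1]] <- data.frame(
        step = ti, age = age, type = "extinction", species = sp$id,
        parent = sp$parent, n_cells = length(sp$last_cells))
      event_cells[[length(event_cells) + 1]] <- sp$last_cells
      spp[[si]] <- sp
    }

    # richness recount
    r <- matrix(0L, grid$nlat, grid$nlon)
    for (sp in spp) {
      if (is.na(sp$extinct_age) && length(sp$cells) > 0)
        r[sp$cells] <- r[sp$cells] + 1L
    }
    richness[, , ti] <- r
  }

  species <- do.call(rbind, lapply(spp, function(s) data.frame(
    id = s$id, parent = s$parent, origin_age = s$origin_age,
    extinct_age = s$extinct_age)))
  events_df <- if (length(events)) do.call(rbind, events) else
    data.frame(step = integer(0), age = numeric(0), type = character(0),
               species = integer(0), parent = integer(0), n_cells = integer(0))
  structure(list(
    richness = richness, events = events_df, event_cells = event_cells,
    species = species, land = series$land, grid = grid,
    times = series$times, spinup = spinup, scenario_id = scenario$id,
    draw = draw), class = "simulation_record")
}

#' @export
print.simulation_record <- function(x, ...) {
  extant <- sum(is.na(x$species$extinct_age))
  cat(sprintf(
    "<simulation_record> %s: %d species total (%d extant), %d steps\n",
    x$scenario_id, nrow(x$species), extant, length(x$times)))
  invisible(x)
}

# Remove occupied-cell rows from a species; track last_cells; optionally
# relabel cluster indices to stay 1..k.
drop_cells <- function(sp, rows, relabel = FALSE) {
  if (length(rows) == 0) return(sp)
  if (length(sp$cells) > 0) sp$last_cells <- sp$cells
  keep <- setdiff(seq_along(sp$cells), rows)
  sp$cells <- sp$cells[keep]
  sp$N <- sp$N[keep]
  sp$Topt <- sp$Topt[keep]
  sp$Popt <- sp$Popt[keep]
  if (!is.null(sp$colonized)) sp$colonized <- sp$colonized[keep]
  if (!is.null(sp$clust)) {
    sp$clust <- sp$clust[keep]
    if (relabel && length(sp$clust) > 0 && !is.null(sp$div) &&
        nrow(sp$div) > 0) {
      present <- sort(unique(sp$clust))
      sp$div <- sp$div[present, present, drop = FALSE]
      sp$resid <- sp$resid[present]
      sp$clust <- match(sp$clust, present)
    } else if (length(sp$clust) == 0) {
      sp$div <- matrix(0, 0, 0); sp$resid <- numeric(0)
    }
  }
  sp
}
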