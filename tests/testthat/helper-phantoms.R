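# Shared phantom builders and independent oracles for the test suite.

# straight 50 mm tube along x on a 60 x 9 x 9 unit grid
straight_tube_spec <- function(velocity_mm_s, noise_sigma = 0, seed = 1L,
                               n_frames = 30L, dt = 2, inlet_arrival_s = 4) {
  seg <- vessel_segment(c(4, 4, 4), c(54, 4, 4), radius_mm = 1.5,
                        velocity_mm_s = velocity_mm_s,
                        inlet_arrival_s = inlet_arrival_s)
  phantom_spec(c(60, 9, 9), spacing = c(1, 1, 1), dt = dt,
               n_frames = n_frames, segments = list(seg),
               noise_sigma = noise_sigma, seed = seed)
}

# Y-shaped tree: proximal/thrombus/mother trunk plus two daughters
y_tree_spec <- function(v1 = 5, v2 = -5, a1 = 5.6, a2 = 5.0,
                        noise_sigma = 0, seed = 1L) {
  segs <- list(
    vessel_segment(c(4, 20, 8), c(12, 20, 8), 1.5, 10, inlet_arrival_s = 4),
    vessel_segment(c(12, 20, 8), c(16, 20, 8), 1.5, 10, inlet_arrival_s = 4.8,
                   enhancement = 0.4),
    vessel_segment(c(16, 20, 8), c(20, 20, 8), 1.5, 10, inlet_arrival_s = 5.2),
    vessel_segment(c(20, 20, 8), c(34, 30, 8), 1.5, v1, inlet_arrival_s = a1),
    vessel_segment(c(20, 20, 8), c(34, 10, 8), 1.5, v2, inlet_arrival_s = a2))
  phantom_spec(c(40, 40, 17), segments = segs, noise_sigma = noise_sigma,
               seed = seed)
}

y_tree_markers <- function() {
  marker_set(c(6, 21, 9), c(15, 21, 9), list(c(32, 29, 9), c(32, 12, 9)))
}

# continuous gamma-variate TAC sampled on an arbitrary grid
gamma_tac <- function(times, arrival_s, amplitude = 400, t_peak = 6,
                      alpha = 3, arclength_mm = NA_real_,
                      state = "conditioned") {
  tac(times, gamma_variate(times - arrival_s, amplitude, t_peak, alpha),
      arclength_mm = arclength_mm, state = state)
}

# ---- independent shortest-path oracle (Bellman-Ford) ----------------------
# from/to: vertex ids 1..n of an undirected edge list with weights w.
# Returns the distance vector from src. Algorithmically independent of the
# Dijkstra engine used by min_cost_path: full relaxation sweeps to fixpoint.
oracle_shortest_dist <- function(from, to, w, n, src) {
  ft <- c(from, to); tt <- c(to, from); ww <- c(w, w)
  dist <- rep(Inf, n)
  dist[src] <- 0
  repeat {
    cand <- dist[ft] + ww
    ## min of cand grouped by target vertex: sort so the first hit per
    ## vertex is the group minimum
    o <- order(tt, cand)
    first <- !duplicated(tt[o])
    newdist <- dist
    tgt <- tt[o][first]; val <- cand[o][first]
    newdist[tgt] <- pmin(newdist[tgt], val)
    if (all(newdist >= dist - 1e-12)) break
    dist <- newdist
  }
  dist
}

# ---- dense cross-correlation delay oracle ---------------------------------
# Normalized cross-correlation of two continuous curves sampled on a 0.01 s
# grid; exhaustive argmax over the lag window. Independent of xcorr_delay.
oracle_dense_delay <- function(fun1, fun2, duration, lag_max,
                               grid_s = 0.01) {
  tt <- seq(0, duration, by = grid_s)
  a <- fun1(tt); b <- fun2(tt)
  lags <- seq(-lag_max, lag_max, by = grid_s)
  n <- length(tt)
  cc <- vapply(round(lags / grid_s), function(l) {
    if (l >= 0) {
      x <- b[(1 + l):n]; y <- a[1:(n - l)]
    } else {
      x <- b[1:(n + l)]; y <- a[(1 - l):n]
    }
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, 1)
  lags[which.max(cc)]
}

# random 26-connected voxel graph in a small grid with random intensities;
# returns the skeleton_graph plus a t-MIP-like volume
random_voxel_instance <- function(seed, dim = c(8, 8, 8), density = 0.7) {
  set.seed(seed)
  arr <- array(runif(prod(dim)) < density, dim)
  g <- voxel_graph(arr, spacing = c(1, 1, 1))
  vol <- volume3d(array(runif(prod(dim), 50, 450), dim), c(1, 1, 1))
  list(graph = g, tmip = vol)
}
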