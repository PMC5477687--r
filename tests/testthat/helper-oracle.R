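# Naive from-scratch seeded-region-growing oracle.
#
# Independent of the package implementation: every iteration rebuilds the
# frontier (all unallocated valid pixels 8-adjacent to the region) by a full
# image scan and recomputes every deviation from the current region mean.
# Ties are resolved toward the smallest (row, col) in row-major order, the
# documented tie-break. Quadratic and slow on purpose.
srg_oracle <- function(vals, seed, t_t, radius = 0L, max_frac = 1) {
  nr <- nrow(vals); nc <- ncol(vals)
  valid <- is.finite(vals)
  region <- matrix(FALSE, nr, nc)
  for (r in max(1L, seed[1] - radius):min(nr, seed[1] + radius))
    for (c in max(1L, seed[2] - radius):min(nc, seed[2] + radius))
      if (valid[r, c]) region[r, c] <- TRUE
  max_size <- max(1L, floor(max_frac * nr * nc))
  repeat {
    if (sum(region) >= max_size) break
    H <- matrix(integer(0), 0L, 2L)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {   # row-major scan
      if (region[r, c] || !valid[r, c]) next
      adj <- FALSE
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- c + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && region[rr, cc])
          adj <- TRUE
      }
      if (adj) H <- rbind(H, c(r, c))
    }
    if (nrow(H) == 0L) break
    mu <- mean(vals[region])
    delta <- abs(vals[H] - mu)
    if (min(delta) > t_t) break
    z <- H[which(delta == min(delta))[1L], ]   # first hit is row-major minimal
    region[z[1L], z[2L]] <- TRUE
  }
  region
}

# Random small temperature frame on a 0.25 C grid. Quarter-degrees are exact
# binary fractions, so region means are identical no matter the summation
# order and oracle comparisons test the algorithm, not floating-point
# accumulation noise; the coarse grid also makes delta ties common, so the
# row-major tie-break is genuinely exercised. Optionally knocks out a few
# pixels as invalid.
random_small_frame <- function(max_dim = 7L, invalid_prob = 0.05) {
  nr <- sample(2:max_dim, 1L)
  nc <- sample(2:max_dim, 1L)
  v <- matrix(sample(seq(30, 37, by = 0.25), nr * nc, replace = TRUE), nr, nc)
  v[runif(nr * nc) < invalid_prob] <- NA_real_
  if (!any(is.finite(v))) v[1L, 1L] <- 33
  v
}

# pick a random valid seed pixel
random_seed_px <- function(vals) {
  ok <- which(is.finite(vals), arr.ind = TRUE)
  ok[sample(nrow(ok), 1L), ]
}

# standard test scene: one left-side step-edge plateau, fiducials well clear
test_scene <- function(noise_sd_c = 0.1, n_frames = 3L, seed = 1L,
                       edge_width_px = 0, delta_t_c = 2,
                       drift_px_per_frame = c(0, 0), px_per_cm = 4,
                       dims = c(96, 128), center = c(40, 80),
                       semi_axes = c(8, 11), origin_px = c(24, 24)) {
  hs <- hotspot_spec(center = center, semi_axes = semi_axes,
                     delta_t_c = delta_t_c, edge_width_px = edge_width_px,
                     side = "left")
  scene_spec(dims = dims, hotspots = list(hs), noise_sd_c = noise_sd_c,
             n_frames = n_frames, seed = seed, px_per_cm = px_per_cm,
             origin_px = origin_px, drift_px_per_frame = drift_px_per_frame)
}

test_window <- function() search_window(25, 70, 55, 110, side = "left")
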