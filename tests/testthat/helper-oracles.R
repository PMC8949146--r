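# Independent oracles and fixture builders shared by the test files.
# Everything here deliberately uses the dumbest possible algorithm
# (explicit loops, image enumeration) so it cannot share a defect with the
# implementation it checks.

# minimum-image distance by brute-force enumeration of all 27 neighbour
# images
brute_min_image <- function(p1, p2, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- p1 - p2 + c(i, j, k) * box
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# RDF raw pair counts by an explicit double loop over frames, A atoms and
# B atoms, binned with findInterval on explicit breaks
brute_rdf_counts <- function(traj, sel_A, sel_B, r_max, delta_r) {
  nbins <- as.integer(ceiling(r_max / delta_r - 1e-9))
  breaks <- (0:nbins) * delta_r
  counts <- numeric(nbins)
  for (f in traj$frames) {
    for (a in sel_A) {
      for (b in sel_B) {
        d <- minimum_image_distance(f$positions[a, ], f$positions[b, ], f$box)
        if (d < r_max) {
          bin <- findInterval(d, breaks, rightmost.closed = FALSE)
          if (bin >= 1 && bin <= nbins) counts[bin] <- counts[bin] + 1
        }
      }
    }
  }
  counts
}

# random small test system: n molecules of two species, one site each
random_small_system <- function(n_a, n_b, box, n_frames, seed, dt = 1) {
  set.seed(seed)
  n <- n_a + n_b
  atoms <- data.frame(
    molecule_id = seq_len(n),
    species = rep(c("SPA", "SPB"), c(n_a, n_b)),
    site_name = rep(c("X", "Y"), c(n_a, n_b))
  )
  sys <- system_map(atoms)
  frames <- lapply(seq_len(n_frames), function(k) {
    md_frame((k - 1) * dt, matrix(runif(3 * n), ncol = 3) %*% diag(box), box)
  })
  md_trajectory(sys, frames, dt = dt)
}

# single-frame system with explicit positions for hand-constructed cases
fixed_frame_system <- function(atoms, positions, box) {
  sys <- system_map(atoms)
  list(system = sys,
       traj = md_trajectory(sys, list(md_frame(0, positions, box)), dt = 1))
}

# logical state vector -> bond_timeline with synthetic distances (bound
# frames at 1.8 A, unbound at 6 A)
timeline_from_states <- function(states, cutoff = 2.5) {
  bond_timeline(ifelse(states, 1.8, 6), cutoff = cutoff)
}

# small default-composition synthetic run, cached per session
small_synthetic_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(seed = 42, n_frames = 400, dt = 0.1)
      cache <<- c(generate_synthetic(cfg), list(config = cfg))
    }
    cache
  }
})
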