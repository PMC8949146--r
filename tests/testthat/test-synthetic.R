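# Synthetic bilayer generator: composition, geometry, reproducibility and
# the statistical contracts downstream estimators rely on.

test_that("default system reproduces the study composition", {
  run <- small_synthetic_run()
  at <- run$system$atoms
  mol <- unique(at[, c("molecule_id", "species")])
  counts <- table(mol$species)
  expect_equal(unname(counts[["DOPC"]]), 112)
  expect_equal(unname(counts[["DOPS"]]), 28)
  expect_equal(unname(counts[["CHOL"]]), 60)
  expect_equal(run$system$per_leaflet_count, 100)
  expect_equal(sum(mol$species == "DBD3"), 1)
})

test_that("leaflet planes sit at +/- leaflet_z_offset giving the target thickness", {
  cfg <- synthetic_config(seed = 9, n_frames = 2)
  bs <- build_system(cfg)
  at <- bs$system$atoms
  leaf <- bs$system$leaflet$leaflet[match(at$molecule_id,
                                          bs$system$leaflet$molecule_id)]
  z <- bs$frame$positions[, 3]
  up <- at$site_name == "P" & leaf == "upper"
  lo <- at$site_name == "P" & leaf == "lower"
  # per-molecule z jitter (sd 0.5) averages out over 140 phosphorus sites
  expect_lt(abs(mean(z[up]) - mean(z[lo]) - 43.0), 0.35)
})

test_that("composition scales with the leaflet count and rejects crowded boxes", {
  cfg10 <- synthetic_config(seed = 1, n_lipid_per_leaflet = 10, n_frames = 2)
  bs <- build_system(cfg10)
  mol <- unique(bs$system$atoms[, c("molecule_id", "species")])
  expect_equal(sum(mol$species %in% c("DOPC", "DOPS", "CHOL")), 20)

  crowded <- synthetic_config(seed = 1, n_lipid_per_leaflet = 400L,
                              box = c(30, 30, 95.7), n_frames = 2)
  expect_error(build_system(crowded), "too small")
})

test_that("identical seed and config give bit-identical trajectories", {
  cfg <- synthetic_config(seed = 7, n_frames = 50, dt = 0.1)
  r1 <- generate_synthetic(cfg)
  r2 <- generate_synthetic(cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$timelines, r2$timelines)

  cfg2 <- synthetic_config(seed = 8, n_frames = 50, dt = 0.1)
  r3 <- generate_synthetic(cfg2)
  expect_false(identical(r1$trajectory, r3$trajectory))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(generate_synthetic(synthetic_config(seed = 5, n_frames = 10)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("ideal-gas frames are uniform, in-box and reproducible", {
  ig <- ideal_gas_frame(2, 2, c(20, 30, 40), seed = 3)
  expect_equal(nrow(ig$frame$positions), 4)
  expect_true(all(ig$frame$positions >= 0))
  expect_true(all(sweep(ig$frame$positions, 2, c(20, 30, 40), "<=")))
  ig2 <- ideal_gas_frame(2, 2, c(20, 30, 40), seed = 3)
  expect_identical(ig$frame, ig2$frame)
})

test_that("absorbing kinetics behave as stated", {
  # k_off = 0, start bound: bound for all frames
  pt <- simulate_pair_timeline(k_on = 1, k_off = 0, dt = 0.01, n_frames = 500,
                               seed = 2, start_bound = TRUE)
  expect_true(all(pt$states))
  bound_iv <- pt$intervals[pt$intervals$partner > 0, ]
  expect_equal(nrow(bound_iv), 1)
  # k_on = 0, start unbound: never bound
  pt0 <- simulate_pair_timeline(k_on = 0, k_off = 1, dt = 0.01, n_frames = 500,
                                seed = 2)
  expect_false(any(pt0$states))
  expect_error(simulate_pair_timeline(k_on = 0, k_off = 0, dt = 0.01,
                                      n_frames = 10), "> 0")
  expect_error(simulate_pair_timeline(k_on = 1, k_off = 1, dt = 0,
                                      n_frames = 10), "dt")
})

test_that("bound dwell times recover 1/k_off within three standard errors", {
  k_off <- 0.5
  pt <- simulate_pair_timeline(k_on = 1, k_off = k_off, dt = 0.02,
                               n_frames = 3.5e5, seed = 31)
  iv <- pt$intervals
  dwell <- iv$t_end[iv$partner > 0] - iv$t_start[iv$partner > 0]
  dwell <- dwell[-length(dwell)]  # last interval may be clock-truncated
  expect_gt(length(dwell), 2000)
  se <- stats::sd(dwell) / sqrt(length(dwell))
  expect_lt(abs(mean(dwell) - 1 / k_off), 3 * se)
})

test_that("bound-frame distances follow the configured distribution", {
  pt <- simulate_pair_timeline(k_on = 1, k_off = 0.2, dt = 0.05,
                               n_frames = 2e4, bound_mean = 1.7,
                               bound_sd = 0.1, seed = 13)
  d <- pt$distances[pt$states]
  expect_gt(length(d), 1000)
  sem <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 1.7), 3 * sem)
  expect_true(all(pt$distances[!pt$states] > 2.5))
})

test_that("coordinate-level binding matches its ground-truth timeline exactly", {
  run <- small_synthetic_run()
  tr <- run$trajectory
  sys <- run$system
  for (dn in c("H2", "H4")) {
    di <- run$timelines[[dn]]
    tl <- detect_bonds(tr, di$donor_atom, di$partner_atoms, cutoff = 2.5,
                       pooled = TRUE)[[1]]
    expect_identical(tl$states, di$states)
    # while bound the distance sits in the configured band
    expect_true(all(abs(tl$distances[tl$states] -
                          run$config$bound_distance_mean[[dn]]) < 0.6))
  }
})
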