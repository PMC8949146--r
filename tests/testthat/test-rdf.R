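# Radial distribution functions: pair-count equivalence with brute force,
# closed-form single-pair normalisation, pooling, isotropy and bin-width
# consistency.

test_that("raw pair counts are bit-identical to the brute-force double loop", {
  traj <- random_small_system(6, 30, c(13, 15, 17), n_frames = 10, seed = 41)
  sel_A <- select_sites(traj$system, "SPA", "X")
  sel_B <- select_sites(traj$system, "SPB", "Y")
  rdf <- compute_rdf(traj, sel_A, sel_B, r_max = 6, delta_r = 0.25)
  expect_identical(rdf$raw_counts,
                   brute_rdf_counts(traj, sel_A, sel_B, 6, 0.25))
  expect_equal(rdf$n_A, 6)
  expect_equal(rdf$n_B, 30)
  expect_equal(rdf$n_frames, 10)
})

test_that("a single fixed pair reproduces the closed-form shell normalisation", {
  af <- fixed_frame_system(
    data.frame(molecule_id = 1:2, species = c("SPA", "SPB"),
               site_name = c("X", "Y")),
    rbind(c(0, 0, 0), c(3, 0, 0)), c(20, 20, 20)
  )
  rdf <- compute_rdf(af$traj, 1, 2, r_max = 8, delta_r = 0.2)
  hit <- which(rdf$raw_counts > 0)
  expect_length(hit, 1)
  expect_true(rdf$r_centers[hit] - 0.1 <= 3 && 3 < rdf$r_centers[hit] + 0.1)
  r_c <- rdf$r_centers[hit]
  expect_equal(rdf$g[hit], 8000 / (4 * pi * r_c^2 * 0.2), tolerance = 1e-12)
  expect_true(all(rdf$g[-hit] == 0))
})

test_that("an ideal gas is flat at unity beyond the first bins", {
  traj <- ideal_gas_trajectory(50, 1450, c(50, 50, 50), n_frames = 50, seed = 6)
  sel_A <- select_sites(traj$system, "GASA", "A")
  sel_B <- select_sites(traj$system, "GASB", "B")
  rdf <- compute_rdf(traj, sel_A, sel_B, r_max = 10, delta_r = 0.5)
  far <- rdf$r_centers > 2
  expect_lt(max(abs(rdf$g[far] - 1)), 0.1)
  expect_equal(mean(rdf$g[far]), 1, tolerance = 0.02)
})

test_that("pooled RDFs equal the pooled selection and add up site by site", {
  run <- small_synthetic_run()
  tr <- run$trajectory
  sel_A <- select_sites(run$system, "DBD3", "H2")

  pooled <- pooled_rdf(tr, sel_A, "DOPC", c("O13", "O14"), r_max = 8,
                       delta_r = 0.1)
  expect_equal(pooled$n_B, 224)
  r13 <- pooled_rdf(tr, sel_A, "DOPC", "O13", r_max = 8, delta_r = 0.1)
  r14 <- pooled_rdf(tr, sel_A, "DOPC", "O14", r_max = 8, delta_r = 0.1)
  expect_equal(pooled$raw_counts, r13$raw_counts + r14$raw_counts)

  # single-element pool is the plain RDF
  direct <- compute_rdf(tr, sel_A, select_sites(run$system, "DOPC", "O13"),
                        r_max = 8, delta_r = 0.1)
  expect_identical(r13$g, direct$g)

  expect_error(pooled_rdf(tr, sel_A, "DOPC", character(0)), "empty")
})

test_that("the synthetic first shell peaks at the configured bond length", {
  run <- small_synthetic_run()
  sel_A <- select_sites(run$system, "DBD3", "H2")
  rdf <- pooled_rdf(run$trajectory, sel_A, "DOPC", c("O13", "O14"),
                    delta_r = 0.1)
  r_peak <- rdf$r_centers[which.max(rdf$g)]
  expect_lte(abs(r_peak - 1.7), rdf$delta_r)
})

test_that("g is invariant under 90-degree rotations about z", {
  traj <- random_small_system(4, 20, c(16, 16, 16), n_frames = 5, seed = 51)
  rot <- function(f) md_frame(f$time,
                              cbind(-f$positions[, 2], f$positions[, 1],
                                    f$positions[, 3]),
                              f$box)
  traj_rot <- md_trajectory(traj$system, lapply(traj$frames, rot), dt = traj$dt)
  a <- select_sites(traj$system, "SPA", "X")
  b <- select_sites(traj$system, "SPB", "Y")
  g1 <- compute_rdf(traj, a, b, r_max = 7, delta_r = 0.2)
  g2 <- compute_rdf(traj_rot, a, b, r_max = 7, delta_r = 0.2)
  expect_equal(g1$g, g2$g, tolerance = 1e-12)
})

test_that("halving the bin width preserves the shell integral", {
  traj <- random_small_system(4, 40, c(14, 14, 14), n_frames = 8, seed = 61)
  a <- select_sites(traj$system, "SPA", "X")
  b <- select_sites(traj$system, "SPB", "Y")
  coarse <- compute_rdf(traj, a, b, r_max = 6, delta_r = 0.2)
  fine <- compute_rdf(traj, a, b, r_max = 6, delta_r = 0.1)
  # integral of g 4 pi r^2 (N_B/V) dr over [1, 5] = mean pair count there
  shell_integral <- function(rdf, lo, hi) {
    sel <- rdf$r_centers > lo & rdf$r_centers < hi
    sum(rdf$g[sel] * 4 * pi * rdf$r_centers[sel]^2 * rdf$delta_r) *
      rdf$n_B / rdf$mean_volume
  }
  i1 <- shell_integral(coarse, 1, 5)
  i2 <- shell_integral(fine, 1, 5)
  expect_equal(i2, i1, tolerance = 0.02)
})

test_that("invalid RDF requests are rejected with informative errors", {
  traj <- random_small_system(2, 4, c(10, 10, 10), n_frames = 2, seed = 71)
  a <- select_sites(traj$system, "SPA", "X")
  b <- select_sites(traj$system, "SPB", "Y")
  expect_error(compute_rdf(traj, a, c(b, a[1]), r_max = 4), "overlap")
  expect_error(compute_rdf(traj, a, b, r_max = 6), "half")
  expect_error(compute_rdf(traj, integer(0), b, r_max = 4), "non-empty")
  expect_error(compute_rdf(traj, a, b, r_max = 4, delta_r = 0), "delta_r")
})

test_that("RDF CSV export records curve and normalisation metadata", {
  run <- small_synthetic_run()
  sel_A <- select_sites(run$system, "DBD3", "H2")
  rdf <- pooled_rdf(run$trajectory, sel_A, "DOPC", c("O13", "O14"),
                    r_max = 6, delta_r = 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rdf_csv(rdf, path)
  back <- memdrug:::read_csv_meta(path)
  expect_equal(back$g, rdf$g, tolerance = 1e-9)
  expect_equal(as.numeric(attr(back, "meta")$n_B), 224)
  expect_equal(as.numeric(attr(back, "meta")$n_frames), rdf$n_frames)
})
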