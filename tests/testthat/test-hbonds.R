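# Hydrogen-bond detection, lifetime estimation and bridging.

test_that("distance-criterion detection matches brute-force thresholding", {
  # inclusive boundary and simple cases
  tl <- bond_timeline(c(1.7, 2.5, 2.500001, 6), cutoff = 2.5)
  expect_identical(tl$states, c(TRUE, TRUE, FALSE, FALSE))

  traj <- random_small_system(3, 8, c(9, 9, 9), n_frames = 6, seed = 111)
  dsel <- select_sites(traj$system, "SPA", "X")
  asel <- select_sites(traj$system, "SPB", "Y")
  tls <- detect_bonds(traj, dsel, asel, cutoff = 4)
  expect_length(tls, 3 * 8)
  for (tl in tls) {
    for (k in seq_len(n_frames(traj))) {
      f <- traj$frames[[k]]
      d <- brute_min_image(f$positions[tl$donor, ], f$positions[tl$acceptor, ],
                           f$box)
      expect_equal(tl$distances[k], d, tolerance = 1e-12)
      expect_identical(tl$states[k], d <= 4)
    }
  }
  expect_error(detect_bonds(traj, integer(0), asel), "non-empty")
  expect_error(detect_bonds(traj, dsel, asel, cutoff = 0), "cutoff")
})

test_that("pooled detection takes the per-frame nearest pooled site", {
  traj <- random_small_system(1, 5, c(9, 9, 9), n_frames = 4, seed = 112)
  dsel <- select_sites(traj$system, "SPA", "X")
  asel <- select_sites(traj$system, "SPB", "Y")
  tl <- detect_bonds(traj, dsel, asel, cutoff = 4, pooled = TRUE)[[1]]
  for (k in seq_len(4)) {
    f <- traj$frames[[k]]
    dd <- sapply(asel, function(a) brute_min_image(f$positions[dsel, ],
                                                   f$positions[a, ], f$box))
    expect_equal(tl$distances[k], min(dd), tolerance = 1e-12)
    expect_equal(tl$nearest[k], asel[which.min(dd)])
  }
})

test_that("lifetime arithmetic and merge semantics follow the contract", {
  dt <- 0.1
  # 1000 bound frames, nothing else: one interval of 100 ns -- here scaled:
  tl <- timeline_from_states(rep(TRUE, 1000))
  expect_equal(lifetimes(tl, dt = 0.01, tolerance = 0)$tau, 10.0)

  # bound 10 ns, unbound 0.2 ns, bound 9.8 ns (dt = 0.1)
  states <- c(rep(TRUE, 100), rep(FALSE, 2), rep(TRUE, 98))
  tl <- timeline_from_states(states)
  merged <- lifetimes(tl, dt = dt, tolerance = 0.5)
  expect_equal(merged$n_intervals, 1)
  expect_equal(merged$tau, 20.0)
  split <- lifetimes(tl, dt = dt, tolerance = 0.1)
  expect_equal(split$n_intervals, 2)
  expect_equal(split$tau, 9.9)

  # with zero tolerance the summed durations equal bound frames x dt exactly
  set.seed(5)
  rnd <- timeline_from_states(runif(500) < 0.4)
  ls0 <- lifetimes(rnd, dt = dt, tolerance = 0)
  expect_equal(sum(ls0$intervals$duration), sum(rnd$states) * dt)
})

test_that("tau is non-decreasing in tolerance and bounded by the record", {
  set.seed(6)
  for (rep in 1:5) {
    states <- runif(400) < runif(1, 0.2, 0.7)
    if (!any(states)) states[100] <- TRUE
    tl <- timeline_from_states(states)
    tols <- c(0, 0.1, 0.3, 1, 5, 40)
    taus <- sapply(tols, function(tol) lifetimes(tl, dt = 0.1, tolerance = tol)$tau)
    expect_true(all(diff(taus) >= -1e-12))
    expect_true(all(taus <= 400 * 0.1 + 1e-12))
    # tolerance >= record length merges everything bound into one interval
    expect_equal(lifetimes(tl, dt = 0.1, tolerance = 40)$n_intervals, 1)
  }
})

test_that("never-bound pairs are distinct from zero lifetimes", {
  tl <- timeline_from_states(rep(FALSE, 100))
  ls <- lifetimes(tl, dt = 0.1)
  expect_true(is.na(ls$tau))
  expect_equal(ls$n_intervals, 0)
  expect_true(is.na(ls$mean_distance_bound))
})

test_that("edge-truncated intervals can be excluded", {
  states <- c(rep(TRUE, 50), rep(FALSE, 100), rep(TRUE, 30), rep(FALSE, 100),
              rep(TRUE, 20))
  tl <- timeline_from_states(states)
  with_edges <- lifetimes(tl, dt = 0.1, tolerance = 0)
  expect_equal(with_edges$n_intervals, 3)
  no_edges <- lifetimes(tl, dt = 0.1, tolerance = 0, include_edges = FALSE)
  expect_equal(no_edges$n_intervals, 1)
  expect_equal(no_edges$tau, 3.0)
})

test_that("lifetimes recover the exponential dwell oracle on long timelines", {
  k_off <- 0.1
  pt <- simulate_pair_timeline(k_on = 1, k_off = k_off, dt = 0.01,
                               n_frames = 6e5, seed = 19)
  ls <- lifetimes(bond_timeline(pt$distances), dt = 0.01, tolerance = 0)
  expect_gt(ls$n_intervals, 400)
  se <- stats::sd(ls$intervals$duration) / sqrt(ls$n_intervals)
  expect_lt(abs(ls$tau - 1 / k_off), 3 * se)
})

test_that("the pair table recovers bound distances and ranks lifetimes", {
  run <- small_synthetic_run()
  specs <- list(
    list(label = "H2 / O13-14 DOPC",
         donor = list(species = "DBD3", site = "H2"),
         partner = list(species = "DOPC", sites = c("O13", "O14"))),
    list(label = "H4 / O Cholesterol",
         donor = list(species = "DBD3", site = "H4"),
         partner = list(species = "CHOL", sites = "OH-O"))
  )
  tab <- pair_lifetime_table(run$trajectory, specs, cutoff = 2.5,
                             tolerance = 0)
  expect_equal(tab$pair_label, c("H2 / O13-14 DOPC", "H4 / O Cholesterol"))
  expect_lt(abs(tab$mean_distance_bound[1] - 1.7), 0.05)
  expect_lt(abs(tab$mean_distance_bound[2] - 2.05), 0.05)
  # configured mean dwells 30 ns (H2) vs 4 ns (H4): rank must be recovered
  expect_gt(tab$tau[1], tab$tau[2])
  # never-bound pair: NA tau with zero intervals
  specs_nb <- list(list(label = "O11 drug / P DOPS",
                        donor = list(species = "DBD3", site = "O11"),
                        partner = list(species = "DOPS", sites = "P")))
  tab_nb <- pair_lifetime_table(run$trajectory, specs_nb)
  expect_true(is.na(tab_nb$tau))
  expect_equal(tab_nb$n_intervals, 0)
})

test_that("bridges need two drug sites on two distinct partner molecules", {
  atoms <- data.frame(
    molecule_id = c(1, 1, 2, 2, 3),
    species = c("DBD4", "DBD4", "DOPC", "DOPC", "CHOL"),
    site_name = c("H2", "H4", "O13", "O14", "OH-O")
  )
  box <- c(30, 30, 30)
  mk <- function(pos) fixed_frame_system(atoms, pos, box)

  # H2 at 1.7 A from DOPC O13, H4 at 2.0 A from cholesterol OH-O: a bridge
  pos <- rbind(c(10, 10, 10), c(14, 10, 10),
               c(10, 10, 11.7), c(10, 13, 10), c(14, 10, 12))
  fs <- mk(pos)
  dsel <- select_sites(fs$system, "DBD4", c("H2", "H4"))
  psel <- c(select_sites(fs$system, "DOPC", c("O13", "O14")),
            select_sites(fs$system, "CHOL", "OH-O"))
  ev <- detect_bridges(fs$traj, dsel, psel, cutoff = 2.5)
  expect_equal(nrow(ev), 1)
  expect_setequal(c(ev$partner_species_1, ev$partner_species_2),
                  c("DOPC", "CHOL"))
  expect_setequal(c(ev$drug_site_1, ev$drug_site_2), c("H2", "H4"))

  # both drug sites on the same DOPC molecule: not a bridge
  pos_same <- rbind(c(10, 10, 10), c(12.4, 10, 10),
                    c(10, 10, 11.7), c(12.4, 10, 11.7), c(25, 25, 25))
  expect_equal(nrow(detect_bridges(mk(pos_same)$traj, dsel, psel,
                                   cutoff = 2.5)), 0)

  # everything far apart: empty result
  pos_far <- rbind(c(1, 1, 1), c(4, 1, 1), c(10, 10, 10), c(13, 10, 10),
                   c(20, 20, 20))
  expect_equal(nrow(detect_bridges(mk(pos_far)$traj, dsel, psel,
                                   cutoff = 2.5)), 0)
  expect_error(detect_bridges(fs$traj, dsel[1], psel), "two drug sites")
})

test_that("bridge detection matches a brute-force triple loop", {
  set.seed(121)
  atoms <- data.frame(
    molecule_id = c(1, 1, 2, 2, 3, 3, 4),
    species = c("DBD4", "DBD4", "DOPC", "DOPC", "DOPS", "DOPS", "CHOL"),
    site_name = c("H2", "H4", "O13", "O14", "O22", "O32", "OH-O")
  )
  box <- c(8, 8, 8)
  cutoff <- 3
  hits <- 0
  for (rep in 1:40) {
    pos <- matrix(runif(21, 0, 8), ncol = 3)
    fs <- fixed_frame_system(atoms, pos, box)
    dsel <- 1:2
    psel <- 3:7
    ev <- detect_bridges(fs$traj, dsel, psel, cutoff = cutoff)
    # oracle: nearest bound partner per drug site, then molecule distinctness
    bound_to <- sapply(dsel, function(d) {
      dd <- sapply(psel, function(a) brute_min_image(pos[d, ], pos[a, ], box))
      if (min(dd) <= cutoff) psel[which.min(dd)] else NA
    })
    expected <- !any(is.na(bound_to)) &&
      atoms$molecule_id[bound_to[1]] != atoms$molecule_id[bound_to[2]]
    expect_equal(nrow(ev) == 1, expected)
    hits <- hits + nrow(ev)
  }
  expect_gt(hits, 0)  # the random battery must actually exercise bridges
})
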