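# Synthetic trajectory generator.
#
# Emulates the statistical structure the downstream estimators assume:
# a two-leaflet DOPC/DOPS/cholesterol pseudo-bilayer (56:14:30 per leaflet)
# with one drug molecule whose donor sites (H2, H4) bind partner oxygens as
# a continuous-time two-state process with a prescribed bond-length
# distribution. No forces, no thermostat — the generator reproduces the
# shapes the analyses measure (first-shell distances, dwell times, leaflet
# geometry), not the physics that causes them.

#' Configuration for the synthetic bilayer generator
#'
#' Defaults reproduce the study system: 100 lipid+cholesterol molecules per
#' leaflet at ratio 56 DOPC : 14 DOPS : 30 cholesterol, a 78.1 x 78.1 x
#' 95.7 Angstrom box, leaflet phosphorus planes at +/-21.5 Angstrom (bilayer
#' thickness 43.0 Angstrom), donor H2 binding at 1.7 Angstrom and H4 at
#' 2.05 Angstrom with 0.1 Angstrom spread, and on/off kinetics giving mean
#' bound lifetimes in the 1-70 ns range.
#'
#' @param seed integer RNG seed; the whole trajectory is reproducible from
#'   `(seed, config)`
#' @param n_lipid_per_leaflet lipid+cholesterol molecules per leaflet
#' @param box orthorhombic box lengths in Angstrom
#' @param dt sampling interval in ns
#' @param n_frames number of frames (>= 2)
#' @param bound_distance_mean named numeric, mean donor-partner distance in
#'   Angstrom while bound, per donor site
#' @param bound_distance_sd Gaussian spread of the bound distance, Angstrom
#' @param k_on,k_off named numeric binding/unbinding rates in 1/ns per donor
#'   site (mean unbound dwell `1/k_on`, mean bound dwell `1/k_off`)
#' @param leaflet_z_offset phosphorus plane offset from the midplane,
#'   Angstrom (thickness = twice this)
#' @param area_jitter relative standard deviation of the lateral box area
#'   per frame (0 = constant box)
#' @param thermal_jitter per-atom Gaussian positional jitter per frame,
#'   Angstrom
#' @param partner_species,partner_sites named lists giving, per donor site,
#'   the partner species and the pooled partner site names the donor binds
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(seed = 1L,
                             n_lipid_per_leaflet = 100L,
                             box = c(78.1, 78.1, 95.7),
                             dt = 0.1,
                             n_frames = 6000L,
                             bound_distance_mean = c(H2 = 1.7, H4 = 2.05),
                             bound_distance_sd = 0.1,
                             k_on = c(H2 = 1 / 10, H4 = 1 / 10),
                             k_off = c(H2 = 1 / 30, H4 = 1 / 4),
                             leaflet_z_offset = 21.5,
                             area_jitter = 0.05,
                             thermal_jitter = 0.25,
                             partner_species = list(H2 = "DOPC", H4 = "CHOL"),
                             partner_sites = list(H2 = c("O13", "O14"),
                                                  H4 = "OH-O")) {
  cfg <- list(
    seed = as.integer(seed),
    n_lipid_per_leaflet = as.integer(n_lipid_per_leaflet),
    box = as.numeric(box),
    dt = as.numeric(dt),
    n_frames = as.integer(n_frames),
    bound_distance_mean = bound_distance_mean,
    bound_distance_sd = as.numeric(bound_distance_sd),
    k_on = k_on,
    k_off = k_off,
    leaflet_z_offset = as.numeric(leaflet_z_offset),
    area_jitter = as.numeric(area_jitter),
    thermal_jitter = as.numeric(thermal_jitter),
    partner_species = partner_species,
    partner_sites = partner_sites
  )
  if (cfg$n_frames < 2L) stop("n_frames must be >= 2")
  if (cfg$bound_distance_sd <= 0) stop("bound_distance_sd must be > 0")
  if (any(cfg$k_on < 0) || any(cfg$k_off < 0)) stop("rates must be >= 0")
  if (length(cfg$box) != 3L || any(cfg$box <= 0)) stop("box must be 3 positive lengths")
  class(cfg) <- "synthetic_config"
  cfg
}

# species counts per leaflet at ratio 56:14:30, largest-remainder rounding
leaflet_composition <- function(n) {
  frac <- c(DOPC = 56, DOPS = 14, CHOL = 30) / 100
  base <- floor(frac * n)
  rem <- frac * n - base
  short <- n - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

# local site geometry of one pseudo-lipid; s = +1 upper leaflet (tails point
# down, -z), s = -1 lower. Offsets in Angstrom relative to the P position.
lipid_site_offsets <- function(s) {
  rbind(
    P   = c(0, 0, 0),
    O13 = c(1.2, 0, 0.3 * s),
    O14 = c(-1.2, 0, 0.3 * s),
    O11 = c(0.8, 0.8, -1.5 * s),
    O12 = c(-0.8, 0.8, -1.5 * s),
    O22 = c(0.5, -0.5, -4.0 * s),
    O32 = c(-0.5, 0.5, -4.0 * s)
  )
}

chol_site_offsets <- function(s) {
  rbind(
    `OH-O` = c(0, 0, -0.5 * s),
    `OH-H` = c(0.95, 0, -0.5 * s)
  )
}

#' Build the synthetic bilayer system and its initial frame
#'
#' Places two leaflets of pseudo-lipids on jittered square lattices at
#' z = +/- `leaflet_z_offset`; each phospholipid carries sites P (on the
#' leaflet plane), O13/O14 (head, near the plane), O11/O12 and O22/O32
#' (displaced toward the bilayer centre); cholesterol carries hydroxyl
#' OH-O/OH-H. One drug molecule (species DBD3 by default vocabulary) with
#' sites H2, H4, O11, O12 sits at the upper interface.
#'
#' @param config a `synthetic_config`
#' @param drug_species species label of the single drug molecule
#' @return list with elements `system` (a `system_map`) and `frame` (the
#'   initial `md_frame`)
#' @export
build_system <- function(config, drug_species = "DBD3") {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_lipid_per_leaflet
  box <- config$box
  grid <- ceiling(sqrt(n))
  spacing <- min(box[1], box[2]) / grid
  if (spacing < 4) {
    stop("box too small to place ", n, " molecules per leaflet without ",
         "overlap (lattice spacing ", round(spacing, 2), " < 4 Angstrom)")
  }

  comp <- leaflet_composition(n)
  species_seq <- rep(c("DOPC", "DOPS", "CHOL"), comp)

  rng <- local_rng(config$seed, 101L)
  rows <- list()
  pos <- list()
  mol_id <- 0L

  for (leaf in c("upper", "lower")) {
    s <- if (leaf == "upper") 1 else -1
    z_leaf <- s * config$leaflet_z_offset
    # interleave species over the lattice deterministically
    ord <- sample_rng(rng, n)
    sp_here <- species_seq[ord]
    for (i in seq_len(n)) {
      mol_id <- mol_id + 1L
      gx <- (i - 1L) %% grid
      gy <- (i - 1L) %/% grid
      centre <- c((gx + 0.5) * box[1] / grid - box[1] / 2,
                  (gy + 0.5) * box[2] / grid - box[2] / 2,
                  z_leaf)
      centre[1:2] <- centre[1:2] + runif_rng(rng, 2, -0.15, 0.15) * spacing
      centre[3] <- centre[3] + rnorm_rng(rng, 1, 0, 0.5)
      off <- if (sp_here[i] == "CHOL") chol_site_offsets(s) else lipid_site_offsets(s)
      rows[[mol_id]] <- data.frame(
        molecule_id = mol_id, species = sp_here[i],
        site_name = rownames(off), stringsAsFactors = FALSE
      )
      pos[[mol_id]] <- sweep(off, 2L, centre, "+")
    }
  }

  # one drug molecule at the upper interface, slightly above the P plane
  mol_id <- mol_id + 1L
  drug_centre <- c(0, 0, config$leaflet_z_offset + 2.5)
  drug_off <- rbind(H2 = c(0, 0, 0), H4 = c(2.2, 0, 0.3),
                    O11 = c(1.0, 1.4, 0.8), O12 = c(1.4, -1.2, 0.8))
  rows[[mol_id]] <- data.frame(
    molecule_id = mol_id, species = drug_species,
    site_name = rownames(drug_off), stringsAsFactors = FALSE
  )
  pos[[mol_id]] <- sweep(drug_off, 2L, drug_centre, "+")

  atoms <- do.call(rbind, rows)
  mol <- unique(atoms[, c("molecule_id", "species")])
  leaf_lab <- ifelse(mol$species %in% c("DOPC", "DOPS", "CHOL"),
                     ifelse(mol$molecule_id <= n, "upper", "lower"), "none")
  sys <- system_map(atoms,
                    leaflet = data.frame(molecule_id = mol$molecule_id,
                                         leaflet = leaf_lab))
  frame <- md_frame(0, do.call(rbind, pos), box)
  list(system = sys, frame = frame)
}

# --- small deterministic RNG wrapper ---------------------------------------
# Keeps generator streams isolated from the caller's RNG state.
local_rng <- function(seed, stream = 0L) {
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed((as.integer(seed) + 1000003L * stream) %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  })
  eval(expr)
}

runif_rng <- function(rng, n, min = 0, max = 1) with_rng(rng, stats::runif(n, min, max))
rnorm_rng <- function(rng, n, mean = 0, sd = 1) with_rng(rng, stats::rnorm(n, mean, sd))
rexp_rng <- function(rng, n, rate = 1) with_rng(rng, stats::rexp(n, rate))
sample_rng <- function(rng, n) with_rng(rng, sample.int(n))

# ---------------------------------------------------------------------------

#' Simulate a two-state (bound/unbound) continuous-time process
#'
#' Alternating-renewal simulation of a donor with one or more partners under
#' competing-risks binding: unbound dwell is exponential with rate
#' `sum(k_on)`, the binding partner is chosen with probability proportional
#' to its `k_on`, and the bound dwell at partner j is exponential with rate
#' `k_off[j]`. With a single partner this is exactly the independent
#' two-state chain with rates `k_on`/`k_off`.
#'
#' @param k_on,k_off numeric rate vectors (1/ns), one entry per partner
#' @param total_time length of the simulated clock, ns
#' @param rng RNG environment from `local_rng()`
#' @param start_bound start in the bound state of partner 1?
#' @return `data.frame` with columns `partner` (0 = unbound), `t_start`,
#'   `t_end` on the continuous clock
#' @export
simulate_two_state <- function(k_on, k_off, total_time, rng,
                               start_bound = FALSE) {
  k_on <- as.numeric(k_on); k_off <- as.numeric(k_off)
  if (sum(k_on) + sum(k_off) <= 0) stop("k_on + k_off must be > 0 for some partner")
  t <- 0
  partner <- if (start_bound) 1L else 0L
  out_p <- integer(0); out_s <- numeric(0); out_e <- numeric(0)
  K_on <- sum(k_on)
  while (t < total_time) {
    if (partner == 0L) {
      dwell <- if (K_on > 0) rexp_rng(rng, 1, K_on) else Inf
      nxt <- if (K_on > 0) {
        if (length(k_on) == 1L) 1L else
          with_rng(rng, sample.int(length(k_on), 1L, prob = k_on))
      } else 0L
    } else {
      rate <- k_off[partner]
      dwell <- if (rate > 0) rexp_rng(rng, 1, rate) else Inf
      nxt <- 0L
    }
    t_end <- min(t + dwell, total_time)
    out_p <- c(out_p, partner); out_s <- c(out_s, t); out_e <- c(out_e, t_end)
    t <- t_end
    partner <- nxt
  }
  data.frame(partner = out_p, t_start = out_s, t_end = out_e)
}

# state of the alternating process at each frame time
states_at_times <- function(intervals, times) {
  idx <- findInterval(times, intervals$t_start)
  idx[idx < 1L] <- 1L
  intervals$partner[idx]
}

#' Simulate a single donor-partner distance timeline
#'
#' The scalar engine behind `simulate_binding()`: a two-state process
#' sampled on the frame grid, emitting the donor-partner distance per frame
#' (bound: `|N(bound_mean, bound_sd)|`; unbound: uniform in
#' `unbound_range`, well above any bond cutoff). Used directly when only
#' the timeline — not full coordinates — is needed, e.g. for long lifetime
#' calibration runs.
#'
#' @param k_on,k_off rates in 1/ns (scalars)
#' @param dt frame spacing, ns
#' @param n_frames number of frames
#' @param bound_mean,bound_sd bound-distance distribution, Angstrom
#' @param unbound_range distance range while unbound, Angstrom
#' @param seed integer seed
#' @param start_bound start bound?
#' @return list with `times` (ns), `distances` (Angstrom), `states`
#'   (logical, frame-grid ground truth), `intervals` (continuous-clock
#'   ground truth from `simulate_two_state`)
#' @export
simulate_pair_timeline <- function(k_on, k_off, dt, n_frames,
                                   bound_mean = 1.7, bound_sd = 0.1,
                                   unbound_range = c(4.5, 8), seed = 1L,
                                   start_bound = FALSE) {
  if (dt <= 0) stop("dt must be > 0")
  rng <- local_rng(seed, 7L)
  times <- (seq_len(n_frames) - 1L) * dt
  total_time <- (n_frames - 1L) * dt + dt / 2
  iv <- simulate_two_state(k_on, k_off, total_time, rng, start_bound = start_bound)
  st <- states_at_times(iv, times) > 0L
  d <- numeric(n_frames)
  nb <- sum(st)
  if (nb > 0) d[st] <- abs(rnorm_rng(rng, nb, bound_mean, bound_sd))
  if (nb < n_frames) d[!st] <- runif_rng(rng, n_frames - nb,
                                         unbound_range[1], unbound_range[2])
  list(times = times, distances = d, states = st, intervals = iv)
}

#' Simulate binding dynamics on the synthetic bilayer
#'
#' Produces a full coordinate trajectory plus per-pair ground-truth bond
#' timelines. Each configured donor site of the drug binds one pooled
#' partner (the nearest molecule of the configured partner species in the
#' upper leaflet): while bound the donor is placed collinearly beyond its
#' partner oxygen at a distance drawn from `|N(mean, sd)|` (so the
#' equivalent twin oxygen of the same molecule stays farther away and other
#' partner oxygens stay >= 4 Angstrom away); while unbound the donor
#' performs a uniform random walk with reflecting walls in the interfacial
#' slab, excluded from coming within 4 Angstrom of its partner sites. Lipid
#' and cholesterol atoms get per-frame Gaussian thermal jitter; the lateral
#' box breathes with relative area jitter `area_jitter`.
#'
#' @param system,frame0 output of `build_system()`
#' @param config the `synthetic_config` used to build the system
#' @return list with `trajectory` (an `md_trajectory`) and `timelines`
#'   (named list per donor site: `partner_molecule`, `partner_sites`,
#'   ground-truth `intervals` on the continuous clock and `states` on the
#'   frame grid)
#' @export
simulate_binding <- function(system, frame0, config) {
  stopifnot(inherits(system, "system_map"), inherits(frame0, "md_frame"),
            inherits(config, "synthetic_config"))
  if (config$dt <= 0) stop("dt must be > 0")
  donors <- names(config$partner_species)
  if (sum(config$k_on[donors]) + sum(config$k_off[donors]) <= 0) {
    stop("k_on + k_off must be > 0 for at least one donor")
  }

  at <- system$atoms
  drug_species <- unique(at$species[grepl("^DBD", at$species)])
  if (length(drug_species) != 1L) stop("system must contain exactly one drug species")

  nfr <- config$n_frames
  dt <- config$dt
  times <- (seq_len(nfr) - 1L) * dt
  base <- frame0$positions
  box0 <- frame0$box

  rng <- local_rng(config$seed, 202L)

  # choose the bound partner molecule per donor: nearest upper-leaflet
  # molecule of the partner species (by its first pooled site)
  upper_ids <- system$leaflet$molecule_id[system$leaflet$leaflet == "upper"]
  donor_info <- list()
  for (dn in donors) {
    d_idx <- select_sites(system, drug_species, dn)
    sp <- config$partner_species[[dn]]
    sites <- config$partner_sites[[dn]]
    cand <- which(at$species == sp & at$site_name == sites[1] &
                    at$molecule_id %in% upper_ids)
    if (length(cand) == 0L) stop("no upper-leaflet ", sp, " partner for donor ", dn)
    dists <- min_image_dist_to_many(base[d_idx, ], base[cand, , drop = FALSE], box0)
    pm <- at$molecule_id[cand[which.min(dists)]]
    p_idx <- which(at$molecule_id == pm & at$site_name %in% sites)
    # exclusion set: every oxygen of the partner species/site pool, so the
    # unbound walker never sits at bond distance from any of them
    x_idx <- which(at$species == sp & at$site_name %in% sites)
    # continuous-clock two-state ground truth for this donor
    iv <- simulate_two_state(config$k_on[[dn]], config$k_off[[dn]],
                             (nfr - 1L) * dt + dt / 2, rng)
    donor_info[[dn]] <- list(
      donor_atom = d_idx[1], partner_molecule = pm, partner_atoms = p_idx,
      exclusion_atoms = x_idx, partner_sites = sites, intervals = iv,
      states = states_at_times(iv, times) > 0L
    )
  }

  # pre-draw per-frame stochastic ingredients
  area_scale <- if (config$area_jitter > 0) {
    sqrt(pmax(1 + rnorm_rng(rng, nfr, 0, config$area_jitter), 0.5))
  } else rep(1, nfr)

  lipid_atoms <- which(at$species %in% c("DOPC", "DOPS", "CHOL"))
  n_lip_at <- length(lipid_atoms)

  z_top <- config$leaflet_z_offset + 6
  z_bot <- config$leaflet_z_offset - 2

  frames <- vector("list", nfr)
  # walker state per donor (positions while unbound)
  walker <- lapply(donor_info, function(di) base[di$donor_atom, ])

  for (k in seq_len(nfr)) {
    p <- base
    if (config$thermal_jitter > 0) {
      p[lipid_atoms, ] <- p[lipid_atoms, ] +
        matrix(rnorm_rng(rng, 3L * n_lip_at, 0, config$thermal_jitter),
               ncol = 3L)
    }
    box <- c(box0[1] * area_scale[k], box0[2] * area_scale[k], box0[3])

    for (dn in donors) {
      di <- donor_info[[dn]]
      if (di$states[k]) {
        # bound: place donor collinearly beyond the first pooled oxygen,
        # pointing away from its twin so the twin sits ~2.4 A farther
        pa <- p[di$partner_atoms[1], ]
        axis <- if (length(di$partner_atoms) > 1L) {
          v <- pa - p[di$partner_atoms[2], ]
          nv <- sqrt(sum(v * v)); if (nv < 1e-9) c(1, 0, 0) else v / nv
        } else c(0, 0, 1)
        d <- abs(rnorm_rng(rng, 1, config$bound_distance_mean[[dn]],
                           config$bound_distance_sd))
        pos <- pa + axis * d
        p[di$donor_atom, ] <- pos
        walker[[dn]] <- pos
      } else {
        # unbound: reflecting random walk in the interfacial slab, kept
        # >= 4 A from this donor's partner oxygens (so unbound frames are
        # never mistaken for bonds and first shells stay attributable)
        excl <- p[di$exclusion_atoms, , drop = FALSE]
        if (k == 1L || di$states[k - 1L]) {
          # just unbound (or unbound start): place beyond the exclusion
          # radius along the axis pointing away from the twin oxygen;
          # fall back to straight above the partner (always clear of the
          # lattice) if that spot is near some other oxygen
          pa <- p[di$partner_atoms[1], ]
          axis <- if (length(di$partner_atoms) > 1L) {
            v <- pa - p[di$partner_atoms[2], ]
            nv <- sqrt(sum(v * v)); if (nv < 1e-9) c(0, 0, 1) else v / nv
          } else c(0, 0, 1)
          cand <- pa + axis * (4.3 + abs(rnorm_rng(rng, 1, 0, 0.4)))
          if (min(min_image_dist_to_many(cand, excl, box)) < 4) {
            cand <- pa + c(0, 0, 4.5)
          }
          walker[[dn]] <- cand
        }
        w <- walker[[dn]]
        cand <- w + runif_rng(rng, 3, -1, 1)
        if (cand[3] > z_top) cand[3] <- 2 * z_top - cand[3]
        if (cand[3] < z_bot) cand[3] <- 2 * z_bot - cand[3]
        # reflect off the 4 A exclusion sphere of the nearest oxygen
        for (try in 1:4) {
          dd <- min_image_dist_to_many(cand, excl, box)
          j <- which.min(dd)
          if (dd[j] >= 4) break
          pn <- excl[j, ]
          cand <- pn + (cand - pn) / max(dd[j], 1e-6) * (8 - dd[j])
        }
        if (min(min_image_dist_to_many(cand, excl, box)) >= 4) {
          walker[[dn]] <- cand  # else stay put: the previous position
                                # already satisfies the exclusion
        }
        p[di$donor_atom, ] <- walker[[dn]]
      }
    }
    frames[[k]] <- md_frame(times[k], p, box)
  }

  list(
    trajectory = md_trajectory(system, frames, dt = dt),
    timelines = donor_info
  )
}

#' Generate a full synthetic run from a configuration
#'
#' Convenience wrapper: `build_system()` then `simulate_binding()`.
#'
#' @param config a `synthetic_config`
#' @return list with `system`, `trajectory`, `timelines`
#' @export
generate_synthetic <- function(config) {
  bs <- build_system(config)
  sim <- simulate_binding(bs$system, bs$frame, config)
  list(system = bs$system, trajectory = sim$trajectory,
       timelines = sim$timelines)
}

#' Ideal-gas frame: uniform positions in a box
#'
#' Reference system for the RDF normalisation: two species (A and B) of
#' i.i.d. uniform points, for which g(r) = 1 at all r.
#'
#' @param n_A,n_B counts of A and B particles (>= 1)
#' @param box box lengths, Angstrom
#' @param seed integer seed
#' @param time frame time stamp, ns
#' @return list with `system` (`system_map`) and `frame` (`md_frame`)
#' @export
ideal_gas_frame <- function(n_A, n_B, box, seed = 1L, time = 0) {
  stopifnot(n_A >= 1L, n_B >= 1L)
  rng <- local_rng(seed, 11L)
  n <- n_A + n_B
  pos <- matrix(runif_rng(rng, 3L * n), ncol = 3L)
  pos <- sweep(pos, 2L, as.numeric(box), "*")
  atoms <- data.frame(
    molecule_id = seq_len(n),
    species = rep(c("GASA", "GASB"), c(n_A, n_B)),
    site_name = rep(c("A", "B"), c(n_A, n_B)),
    stringsAsFactors = FALSE
  )
  list(system = system_map(atoms), frame = md_frame(time, pos, box))
}

#' Ideal-gas trajectory: independent uniform frames
#'
#' @inheritParams ideal_gas_frame
#' @param n_frames number of independent frames
#' @param dt frame spacing, ns
#' @return an `md_trajectory`
#' @export
ideal_gas_trajectory <- function(n_A, n_B, box, n_frames, seed = 1L, dt = 1) {
  first <- ideal_gas_frame(n_A, n_B, box, seed = seed)
  frames <- vector("list", n_frames)
  frames[[1]] <- first$frame
  for (k in seq_len(n_frames - 1L)) {
    f <- ideal_gas_frame(n_A, n_B, box, seed = seed + 7919L * k, time = k * dt)
    frames[[k + 1L]] <- f$frame
  }
  md_trajectory(first$system, frames, dt = dt)
}
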