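# Hydrogen-bond detection, lifetime estimation and bridge analysis.
#
# The bond criterion is distance-only: a donor hydrogen (or oxygen) and a
# partner heavy atom are bound when their minimum-image distance is at or
# below a cutoff (default 2.5 Angstrom, enclosing the observed 1.6-2.1
# Angstrom hydrogen-bond band with margin; no angular criterion is
# imposed). Lifetimes are mean continuous bound intervals with transient
# breaks up to a tolerance merged away.

#' Detect bonds between donor and acceptor selections
#'
#' Per frame, a pair is bound iff its minimum-image distance is `<= cutoff`
#' (boundary inclusive). With `pooled = FALSE` one timeline is produced per
#' (donor, acceptor) pair; with `pooled = TRUE` the acceptor selection is
#' treated as one equivalent pool and each donor gets a single timeline
#' whose per-frame distance is the minimum over the pool (so a swap between
#' equivalent pooled sites never counts as a break).
#'
#' @param traj an `md_trajectory`
#' @param donor_sel,acceptor_sel integer atom selections (non-empty)
#' @param cutoff bond distance cutoff, Angstrom (> 0)
#' @param pooled treat the acceptor selection as one pooled site?
#' @return list of `bond_timeline` objects, each with `donor`, `acceptor`
#'   (atom index, or vector when pooled), `distances` (Angstrom per frame),
#'   `states` (logical per frame), `nearest` (pooled only: index of the
#'   nearest pooled atom per frame), `cutoff`
#' @export
detect_bonds <- function(traj, donor_sel, acceptor_sel, cutoff = 2.5,
                         pooled = FALSE) {
  stopifnot(inherits(traj, "md_trajectory"))
  donor_sel <- as.integer(donor_sel); acceptor_sel <- as.integer(acceptor_sel)
  if (length(donor_sel) == 0L || length(acceptor_sel) == 0L) {
    stop("donor and acceptor selections must be non-empty")
  }
  if (cutoff <= 0) stop("cutoff must be > 0")
  nf <- n_frames(traj)

  timelines <- list()
  for (d in donor_sel) {
    if (pooled) {
      dist <- numeric(nf); nearest <- integer(nf)
      for (k in seq_len(nf)) {
        f <- traj$frames[[k]]
        dd <- min_image_dist_to_many(f$positions[d, ],
                                     f$positions[acceptor_sel, , drop = FALSE],
                                     f$box)
        j <- which.min(dd)
        dist[k] <- dd[j]; nearest[k] <- acceptor_sel[j]
      }
      timelines[[length(timelines) + 1L]] <- structure(
        list(donor = d, acceptor = acceptor_sel, distances = dist,
             states = dist <= cutoff, nearest = nearest, cutoff = cutoff),
        class = "bond_timeline"
      )
    } else {
      for (a in acceptor_sel) {
        dist <- vapply(traj$frames, function(f) {
          minimum_image_distance(f$positions[d, ], f$positions[a, ], f$box)
        }, numeric(1))
        timelines[[length(timelines) + 1L]] <- structure(
          list(donor = d, acceptor = a, distances = dist,
               states = dist <= cutoff, nearest = NULL, cutoff = cutoff),
          class = "bond_timeline"
        )
      }
    }
  }
  timelines
}

#' Build a bond timeline from a precomputed distance series
#'
#' @param distances numeric per-frame distances, Angstrom
#' @param cutoff bond cutoff, Angstrom
#' @return a `bond_timeline`
#' @export
bond_timeline <- function(distances, cutoff = 2.5) {
  structure(
    list(donor = NA_integer_, acceptor = NA_integer_,
         distances = as.numeric(distances),
         states = as.numeric(distances) <= cutoff, nearest = NULL,
         cutoff = cutoff),
    class = "bond_timeline"
  )
}

# maximal runs of TRUE in a logical vector -> data.frame(start, end) in
# frame indices (1-based, inclusive)
bound_runs <- function(states) {
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Mean continuous bond lifetime with transient-break merging
#'
#' Maximal runs of bound frames are merged when separated by unbound gaps
#' of duration `<= tolerance`; the lifetime tau is the mean merged-interval
#' duration, where an interval spanning frames `[s, e]` lasts
#' `(e - s + 1) * dt` (a merged interval includes its internal gaps, so
#' merging two 10 ns intervals across a 0.2 ns break yields one 20.2 ns
#' span counted at its full length). Intervals truncated by the trajectory
#' ends are included by default; excluding them (`include_edges = FALSE`)
#' removes the downward bias when tau is comparable to the trajectory
#' length, at the cost of discarding data.
#'
#' @param timeline a `bond_timeline`
#' @param dt frame spacing, ns
#' @param tolerance maximum unbound-gap duration merged away, ns (>= 0;
#'   default 2)
#' @param include_edges include intervals touching the first or last frame?
#' @return an object of class `lifetime_summary`: `tau` (ns; `NA` when no
#'   interval), `n_intervals`, `intervals` (data.frame start/end frame and
#'   duration), `mean_distance_bound` (Angstrom; `NA` when never bound),
#'   `tolerance_used`, `bound_fraction`
#' @export
lifetimes <- function(timeline, dt, tolerance = 2, include_edges = TRUE) {
  stopifnot(inherits(timeline, "bond_timeline"))
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  st <- timeline$states
  nfr <- length(st)
  runs <- bound_runs(st)

  if (nrow(runs) > 0L && tolerance > 0) {
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1L) {
      for (i in 2:nrow(runs)) {
        gap_frames <- runs$start[i] - merged$end[nrow(merged)] - 1L
        if (gap_frames * dt <= tolerance) {
          merged$end[nrow(merged)] <- runs$end[i]
        } else {
          merged <- rbind(merged, runs[i, ])
        }
      }
    }
    runs <- merged
  }

  if (!include_edges && nrow(runs) > 0L) {
    runs <- runs[runs$start > 1L & runs$end < nfr, , drop = FALSE]
  }

  durations <- (runs$end - runs$start + 1L) * dt
  tau <- if (nrow(runs) > 0L) mean(durations) else NA_real_
  mdb <- if (any(st)) mean(timeline$distances[st]) else NA_real_

  structure(
    list(tau = tau, n_intervals = nrow(runs),
         intervals = cbind(runs, duration = durations),
         mean_distance_bound = mdb, tolerance_used = tolerance,
         bound_fraction = mean(st)),
    class = "lifetime_summary"
  )
}

#' @export
print.lifetime_summary <- function(x, ...) {
  cat(sprintf(
    "<lifetime_summary> tau = %s ns over %d interval(s), mean bound distance = %s A (tolerance %.3g ns)\n",
    if (is.na(x$tau)) "NA" else sprintf("%.3f", x$tau), x$n_intervals,
    if (is.na(x$mean_distance_bound)) "NA" else sprintf("%.3f", x$mean_distance_bound),
    x$tolerance_used))
  invisible(x)
}

#' Lifetime table over a list of donor / pooled-partner pair specs
#'
#' One row per (drug site, pooled partner) pairing: the per-frame bond
#' partner is the nearest pooled site, so a swap between equivalent
#' oxygens of one molecule does not break the bond. Reports the mean bound
#' distance and the mean continuous lifetime tau.
#'
#' @param traj an `md_trajectory`
#' @param pair_specs list of specs, each a list with `label`, `donor =
#'   list(species =, site =)` and `partner = list(species =, sites =)`
#' @param cutoff bond cutoff, Angstrom
#' @param tolerance merge tolerance, ns
#' @param include_edges passed to [lifetimes()]
#' @return `data.frame` with columns `pair_label`, `mean_distance_bound`,
#'   `tau`, `n_intervals`, `bound_fraction`, `tolerance_used`
#' @export
pair_lifetime_table <- function(traj, pair_specs, cutoff = 2.5, tolerance = 2,
                                include_edges = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  rows <- lapply(pair_specs, function(ps) {
    dsel <- select_sites(traj$system, ps$donor$species, ps$donor$site)
    psel <- select_sites(traj$system, ps$partner$species, ps$partner$sites)
    tl <- detect_bonds(traj, dsel[1], psel, cutoff = cutoff, pooled = TRUE)[[1]]
    ls <- lifetimes(tl, dt = traj$dt, tolerance = tolerance,
                    include_edges = include_edges)
    data.frame(
      pair_label = ps$label,
      mean_distance_bound = ls$mean_distance_bound,
      tau = ls$tau,
      n_intervals = ls$n_intervals,
      bound_fraction = ls$bound_fraction,
      tolerance_used = tolerance,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Detect bridging configurations
#'
#' A bridge is a frame where at least two distinct drug sites are
#' simultaneously bound (distance `<= cutoff`) to sites of two distinct
#' partner molecules — e.g. H2 on a DOPC phosphoryl oxygen while H4 holds
#' a cholesterol hydroxyl. Both drug sites on the same partner molecule is
#' not a bridge.
#'
#' @param traj an `md_trajectory`
#' @param drug_sel selection of >= 2 drug donor/acceptor sites
#' @param partner_sel selection of candidate partner sites (any species)
#' @param cutoff bond cutoff, Angstrom
#' @return `data.frame` of events: `frame`, `time`, `drug_site_1`,
#'   `drug_site_2`, `partner_molecule_1`, `partner_species_1`,
#'   `partner_site_1`, and the same for partner 2 (empty when no bridges)
#' @export
detect_bridges <- function(traj, drug_sel, partner_sel, cutoff = 2.5) {
  stopifnot(inherits(traj, "md_trajectory"))
  drug_sel <- as.integer(drug_sel); partner_sel <- as.integer(partner_sel)
  if (length(drug_sel) < 2L) stop("need at least two drug sites to bridge")
  if (length(partner_sel) == 0L) stop("partner selection is empty")
  at <- traj$system$atoms

  ev <- list()
  for (k in seq_len(n_frames(traj))) {
    f <- traj$frames[[k]]
    # bound partner (nearest within cutoff) per drug site, this frame
    bnd <- lapply(drug_sel, function(d) {
      dd <- min_image_dist_to_many(f$positions[d, ],
                                   f$positions[partner_sel, , drop = FALSE],
                                   f$box)
      hit <- which(dd <= cutoff)
      if (length(hit) == 0L) return(NULL)
      partner_sel[hit[which.min(dd[hit])]]
    })
    bound_sites <- which(!vapply(bnd, is.null, logical(1)))
    if (length(bound_sites) < 2L) next
    # all site pairs with distinct partner molecules
    for (i in seq_along(bound_sites)[-length(bound_sites)]) {
      for (j in (i + 1L):length(bound_sites)) {
        a1 <- bnd[[bound_sites[i]]]; a2 <- bnd[[bound_sites[j]]]
        m1 <- at$molecule_id[a1]; m2 <- at$molecule_id[a2]
        if (m1 == m2) next
        ev[[length(ev) + 1L]] <- data.frame(
          frame = k, time = f$time,
          drug_site_1 = at$site_name[drug_sel[bound_sites[i]]],
          drug_site_2 = at$site_name[drug_sel[bound_sites[j]]],
          partner_molecule_1 = m1, partner_species_1 = at$species[a1],
          partner_site_1 = at$site_name[a1],
          partner_molecule_2 = m2, partner_species_2 = at$species[a2],
          partner_site_2 = at$site_name[a2],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(ev) == 0L) {
    return(data.frame(
      frame = integer(0), time = numeric(0),
      drug_site_1 = character(0), drug_site_2 = character(0),
      partner_molecule_1 = integer(0), partner_species_1 = character(0),
      partner_site_1 = character(0),
      partner_molecule_2 = integer(0), partner_species_2 = character(0),
      partner_site_2 = character(0), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, ev)
}
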