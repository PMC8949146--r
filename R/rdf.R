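# Site-site radial distribution functions.
#
# g_AB(r) = V <n_B(r)> / (4 N_B pi r^2 dr), with n_B(r) the number of B
# atoms in the spherical shell [r, r + dr) around an A atom, averaged over
# frames and A atoms; V is the trajectory-averaged box volume and r the bin
# centre. Normalised so that g -> 1 at long distances in a uniform system.

#' Compute a radial distribution function between two selections
#'
#' Distances use the minimum-image convention, so `r_max` may not exceed
#' half the smallest box edge over the trajectory. Binning is half-open
#' `[r, r + delta_r)`; distances at or beyond `r_max` are discarded. The
#' normalisation uses the bin-centre `r^2` (first bin centre `delta_r/2`)
#' and the trajectory-averaged box volume.
#'
#' @param traj an `md_trajectory`
#' @param sel_A,sel_B integer atom selections (non-empty, disjoint);
#'   `sel_B` is the species whose count `N_B` enters the normalisation
#' @param r_max maximum distance, Angstrom
#' @param delta_r bin width, Angstrom (default 0.05, resolving the
#'   1.6-2.1 Angstrom hydrogen-bond band)
#' @return an object of class `rdf_curve`: `r_centers`, `g`, `raw_counts`
#'   (accumulated pair counts per bin over all frames and A atoms),
#'   `delta_r`, `n_A`, `n_B`, `n_frames`, `mean_volume`
#' @export
compute_rdf <- function(traj, sel_A, sel_B, r_max = 12, delta_r = 0.05) {
  stopifnot(inherits(traj, "md_trajectory"))
  sel_A <- as.integer(sel_A); sel_B <- as.integer(sel_B)
  if (length(sel_A) == 0L || length(sel_B) == 0L) stop("selections must be non-empty")
  if (length(intersect(sel_A, sel_B)) > 0L) {
    stop("selections overlap; A and B must be disjoint")
  }
  if (delta_r <= 0) stop("delta_r must be > 0")
  min_edge <- min(vapply(traj$frames, function(f) min(f$box), numeric(1)))
  if (r_max > min_edge / 2 + 1e-9) {
    stop("r_max = ", r_max, " exceeds half the smallest box edge (",
         round(min_edge / 2, 3), "); minimum-image distances are invalid there")
  }

  nbins <- as.integer(ceiling(r_max / delta_r - 1e-9))
  counts <- numeric(nbins)
  vol <- 0
  for (f in traj$frames) {
    posB <- f$positions[sel_B, , drop = FALSE]
    for (a in sel_A) {
      d <- min_image_dist_to_many(f$positions[a, ], posB, f$box)
      d <- d[d < r_max]
      if (length(d) > 0L) {
        bins <- floor(d / delta_r) + 1L
        bins[bins > nbins] <- nbins  # guard against fp edge at r_max
        tb <- tabulate(bins, nbins)
        counts <- counts + tb
      }
    }
    vol <- vol + frame_volume(f)
  }
  nf <- n_frames(traj)
  mean_volume <- vol / nf
  r_centers <- (seq_len(nbins) - 0.5) * delta_r
  mean_nb <- counts / (nf * length(sel_A))
  g <- mean_volume * mean_nb / (4 * length(sel_B) * pi * r_centers^2 * delta_r)

  structure(
    list(r_centers = r_centers, g = g, raw_counts = counts,
         delta_r = delta_r, n_A = length(sel_A), n_B = length(sel_B),
         n_frames = nf, mean_volume = mean_volume),
    class = "rdf_curve"
  )
}

#' @export
print.rdf_curve <- function(x, ...) {
  pk <- which.max(x$g)
  cat("<rdf_curve> ", length(x$g), " bins, dr = ", x$delta_r,
      " A, N_A = ", x$n_A, ", N_B = ", x$n_B, ", peak g = ",
      round(x$g[pk], 3), " at r = ", x$r_centers[pk], " A\n", sep = "")
  invisible(x)
}

#' RDF against a pooled set of equivalent sites
#'
#' Pools equivalent partner sites (e.g. the phosphoryl oxygens O13/O14,
#' treated as one population given their equivalence) into a single B
#' selection with `N_B` equal to the pooled count, then computes the RDF.
#'
#' @param traj an `md_trajectory`
#' @param sel_A selection of A atoms
#' @param species partner species label (single species; pooled sites must
#'   share it)
#' @param site_names character vector of pooled site labels (non-empty)
#' @inheritParams compute_rdf
#' @return an `rdf_curve`
#' @export
pooled_rdf <- function(traj, sel_A, species, site_names, r_max = 12,
                       delta_r = 0.05) {
  if (length(site_names) == 0L) stop("empty site pool")
  if (length(species) != 1L) stop("pooled sites must share one species")
  sel_B <- select_sites(traj$system, species, site_names)
  if (length(sel_B) == 0L) stop("empty pool: no atoms match")
  compute_rdf(traj, sel_A, sel_B, r_max = r_max, delta_r = delta_r)
}

#' Write an RDF curve as CSV with a metadata header
#'
#' Columns `r`, `g`, `raw_count`; `#`-prefixed header lines record the bin
#' width, selection sizes, frame count and mean box volume.
#'
#' @param rdf an `rdf_curve`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_rdf_csv <- function(rdf, path) {
  stopifnot(inherits(rdf, "rdf_curve"))
  write_csv_meta(
    data.frame(r = rdf$r_centers, g = rdf$g, raw_count = rdf$raw_counts),
    path,
    meta = list(delta_r = rdf$delta_r, n_A = rdf$n_A, n_B = rdf$n_B,
                n_frames = rdf$n_frames, mean_volume = rdf$mean_volume)
  )
}
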