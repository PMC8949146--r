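# Bilayer structural metrics: area per lipid and membrane thickness.

#' Area per lipid of one frame
#'
#' Lateral box area divided by the number of lipid + cholesterol molecules
#' in a single leaflet (cholesterol counts toward the divisor by default;
#' exclude it with a lipid-only `per_leaflet_count` if comparing with that
#' convention).
#'
#' @param frame an `md_frame`
#' @param per_leaflet_count lipids + cholesterol in one leaflet (>= 1)
#' @return area per lipid in Angstrom^2
#' @export
#' @examples
#' f <- md_frame(0, matrix(0, 1, 3), c(10, 10, 50))
#' area_per_lipid(f, 1)  # 100
area_per_lipid <- function(frame, per_leaflet_count) {
  stopifnot(inherits(frame, "md_frame"))
  if (length(per_leaflet_count) != 1L || per_leaflet_count < 1) {
    stop("per_leaflet_count must be a positive count")
  }
  frame$box[1] * frame$box[2] / per_leaflet_count
}

#' Bilayer thickness of one frame
#'
#' Difference between the mean z-coordinate of the upper-leaflet phosphorus
#' atoms and that of the lower leaflet. Positive for an intact bilayer with
#' correct leaflet labels; invariant under global translation.
#'
#' @param frame an `md_frame`
#' @param system a `system_map` with leaflet labels
#' @return thickness in Angstrom
#' @export
bilayer_thickness <- function(frame, system) {
  stopifnot(inherits(frame, "md_frame"), inherits(system, "system_map"))
  at <- system$atoms
  leaf <- system$leaflet$leaflet[match(at$molecule_id, system$leaflet$molecule_id)]
  up <- which(at$site_name == "P" & leaf == "upper")
  lo <- which(at$site_name == "P" & leaf == "lower")
  if (length(up) == 0L) stop("upper leaflet has no phosphorus sites")
  if (length(lo) == 0L) stop("lower leaflet has no phosphorus sites")
  mean(frame$positions[up, 3]) - mean(frame$positions[lo, 3])
}

#' Per-frame membrane series with trajectory averages
#'
#' Computes the area-per-lipid and thickness time series over a trajectory
#' together with their means, standard deviations and fluctuation ratios
#' (sd/mean).
#'
#' @param traj an `md_trajectory` whose system carries leaflet labels
#' @param per_leaflet_count optional override of the leaflet count (defaults
#'   to the system map's)
#' @param include_cholesterol if `FALSE`, cholesterol molecules are removed
#'   from the per-leaflet divisor (lipid-only convention)
#' @return an object of class `membrane_series` with `times`,
#'   `area_per_lipid`, `thickness`, `mean_A`, `sd_A`, `mean_dz`, `sd_dz`,
#'   `fluct_A`, `fluct_dz`
#' @export
membrane_series <- function(traj, per_leaflet_count = NULL,
                            include_cholesterol = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  sys <- traj$system
  if (is.null(per_leaflet_count)) {
    if (include_cholesterol) {
      per_leaflet_count <- sys$per_leaflet_count
    } else {
      at <- sys$atoms
      mol <- unique(at[, c("molecule_id", "species")])
      leaf <- sys$leaflet$leaflet[match(mol$molecule_id, sys$leaflet$molecule_id)]
      per_leaflet_count <- max(
        sum(leaf == "upper" & mol$species != "CHOL"),
        sum(leaf == "lower" & mol$species != "CHOL")
      )
    }
  }
  times <- vapply(traj$frames, function(f) f$time, numeric(1))
  A <- vapply(traj$frames, area_per_lipid, numeric(1),
              per_leaflet_count = per_leaflet_count)
  dz <- vapply(traj$frames, bilayer_thickness, numeric(1), system = sys)
  # population sd (divide by n): the series is the full record, not a sample
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(
    list(times = times, area_per_lipid = A, thickness = dz,
         mean_A = mean(A), sd_A = psd(A),
         mean_dz = mean(dz), sd_dz = psd(dz),
         fluct_A = psd(A) / mean(A), fluct_dz = psd(dz) / mean(dz),
         per_leaflet_count = per_leaflet_count),
    class = "membrane_series"
  )
}

#' @export
print.membrane_series <- function(x, ...) {
  cat(sprintf(
    "<membrane_series> %d frames: A = %.2f +/- %.2f A^2 (%.1f%%), dz = %.2f +/- %.2f A (%.1f%%)\n",
    length(x$times), x$mean_A, x$sd_A, 100 * x$fluct_A,
    x$mean_dz, x$sd_dz, 100 * x$fluct_dz))
  invisible(x)
}

#' Write a membrane series as CSV plus a summary JSON
#'
#' @param series a `membrane_series`
#' @param csv_path per-frame CSV path (columns t, A, dz)
#' @param json_path optional summary JSON path (means, sds, fluctuation
#'   ratios)
#' @return `csv_path`, invisibly
#' @export
write_membrane_csv <- function(series, csv_path, json_path = NULL) {
  stopifnot(inherits(series, "membrane_series"))
  write_csv_meta(
    data.frame(t = series$times, A = series$area_per_lipid,
               dz = series$thickness),
    csv_path,
    meta = list(per_leaflet_count = series$per_leaflet_count)
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(mean_A = series$mean_A, sd_A = series$sd_A,
           mean_dz = series$mean_dz, sd_dz = series$sd_dz,
           fluct_A = series$fluct_A, fluct_dz = series$fluct_dz),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(csv_path)
}
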