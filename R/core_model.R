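# Core domain types: system maps, frames, trajectories, site selections and
# periodic-boundary geometry shared by every analysis stage.
#
# Conventions used throughout the package:
#   * coordinates are in Angstrom, times in ns
#   * boxes are orthorhombic, stored as c(Lx, Ly, Lz) in Angstrom
#   * a "selection" is an integer vector of atom indices into the system map

#' Construct a system map
#'
#' A system map is the topology-level description of the simulated system:
#' an ordered atom table (one row per site) plus a leaflet assignment for
#' every lipid and cholesterol molecule. It defines the selections on which
#' all analyses operate.
#'
#' @param atoms `data.frame` with columns `molecule_id` (integer),
#'   `species` (character, e.g. `"DOPC"`, `"DOPS"`, `"CHOL"`, `"DBD1"` ...
#'   `"DBD5"`, `"WATER"`, `"ION"`) and `site_name` (character, e.g. `"P"`,
#'   `"O13"`, `"H2"`). Row order is the atom order of every frame.
#' @param leaflet optional `data.frame` with columns `molecule_id` and
#'   `leaflet` (`"upper"`, `"lower"` or `"none"`). Every lipid/cholesterol
#'   molecule must carry `"upper"` or `"lower"`; drug, water and ion
#'   molecules must carry `"none"` (or be absent, which means `"none"`).
#'
#' @return An object of class `system_map` with elements `atoms`, `leaflet`
#'   and `per_leaflet_count` (lipids + cholesterol in one leaflet).
#' @export
system_map <- function(atoms, leaflet = NULL) {
  stopifnot(is.data.frame(atoms))
  req <- c("molecule_id", "species", "site_name")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0L) {
    stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  }
  atoms$molecule_id <- as.integer(atoms$molecule_id)
  atoms$species <- as.character(atoms$species)
  atoms$site_name <- as.character(atoms$site_name)

  mol <- unique(atoms[, c("molecule_id", "species")])
  if (anyDuplicated(mol$molecule_id)) {
    stop("molecule_id must map to a single species")
  }

  membrane_species <- c("DOPC", "DOPS", "CHOL")
  if (is.null(leaflet)) {
    leaflet <- data.frame(
      molecule_id = mol$molecule_id,
      leaflet = ifelse(mol$species %in% membrane_species, NA_character_, "none"),
      stringsAsFactors = FALSE
    )
  } else {
    stopifnot(is.data.frame(leaflet), all(c("molecule_id", "leaflet") %in% names(leaflet)))
    leaflet <- data.frame(
      molecule_id = as.integer(leaflet$molecule_id),
      leaflet = as.character(leaflet$leaflet),
      stringsAsFactors = FALSE
    )
    leaflet <- merge(mol["molecule_id"], leaflet, by = "molecule_id", all.x = TRUE, sort = TRUE)
    is_mem <- mol$species[match(leaflet$molecule_id, mol$molecule_id)] %in% membrane_species
    leaflet$leaflet[!is_mem & is.na(leaflet$leaflet)] <- "none"
    bad <- !leaflet$leaflet %in% c("upper", "lower", "none") & !is.na(leaflet$leaflet)
    if (any(bad)) stop("leaflet labels must be 'upper', 'lower' or 'none'")
    if (any(leaflet$leaflet[!is_mem] != "none", na.rm = TRUE)) {
      stop("only lipid/cholesterol molecules may carry a leaflet label")
    }
    if (any(is.na(leaflet$leaflet[is_mem]))) {
      stop("every lipid/cholesterol molecule needs a leaflet label ",
           "(or pass leaflet = NULL and call assign_leaflets())")
    }
  }

  n_up <- sum(leaflet$leaflet == "upper", na.rm = TRUE)
  n_lo <- sum(leaflet$leaflet == "lower", na.rm = TRUE)

  structure(
    list(
      atoms = atoms,
      leaflet = leaflet,
      per_leaflet_count = if (n_up > 0L || n_lo > 0L) max(n_up, n_lo) else 0L
    ),
    class = "system_map"
  )
}

#' @export
print.system_map <- function(x, ...) {
  cat("<system_map> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$molecule_id)), " molecules, ",
      x$per_leaflet_count, " lipid+cholesterol per leaflet\n", sep = "")
  invisible(x)
}

#' Number of atoms in a system map
#' @param system a `system_map`
#' @return integer atom count
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Construct a single trajectory frame
#'
#' @param time frame time in ns
#' @param positions numeric matrix, one row per atom, columns x/y/z in
#'   Angstrom
#' @param box numeric length-3 orthorhombic box `c(Lx, Ly, Lz)` in Angstrom.
#'   Triclinic boxes are not supported and are rejected upstream by the
#'   file readers.
#' @return an object of class `md_frame`
#' @export
md_frame <- function(time, positions, box) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an N x 3 matrix")
  if (!all(is.finite(positions))) stop("positions contain non-finite values")
  box <- as.numeric(box)
  if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0)) {
    stop("box must be three positive finite lengths (orthorhombic)")
  }
  structure(
    list(time = as.numeric(time), positions = unname(positions), box = box),
    class = "md_frame"
  )
}

#' Frame volume in cubic Angstrom
#' @param frame an `md_frame`
#' @return numeric volume Lx*Ly*Lz
#' @export
frame_volume <- function(frame) prod(frame$box)

#' Construct a trajectory
#'
#' @param system a `system_map` shared by all frames
#' @param frames list of `md_frame`, times strictly increasing
#' @param dt sampling interval in ns; defaults to the first time difference
#'   (0 for a single-frame trajectory)
#' @return an object of class `md_trajectory`
#' @export
md_trajectory <- function(system, frames, dt = NULL) {
  stopifnot(inherits(system, "system_map"), is.list(frames), length(frames) >= 1L)
  na <- n_atoms(system)
  times <- vapply(frames, function(f) {
    if (!inherits(f, "md_frame")) stop("frames must all be md_frame objects")
    if (nrow(f$positions) != na) {
      stop("frame has ", nrow(f$positions), " atoms but system map has ", na)
    }
    f$time
  }, numeric(1))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (is.null(dt)) dt <- if (length(times) > 1L) times[2] - times[1] else 0
  structure(
    list(system = system, frames = frames, dt = as.numeric(dt)),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory> ", length(x$frames), " frames, dt = ", x$dt, " ns, ",
      n_atoms(x$system), " atoms\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`
#' @return integer frame count
#' @export
n_frames <- function(traj) length(traj$frames)

#' Minimum-image distance between two points in an orthorhombic box
#'
#' Distance under the minimum-image convention: the smallest
#' `|p1 - p2 + n * box|` over all integer translation vectors `n`. For an
#' orthorhombic box this is obtained per component by wrapping each
#' difference into `[-L/2, L/2]`.
#'
#' @param p1,p2 numeric length-3 positions in Angstrom
#' @param box numeric length-3 box lengths in Angstrom, all > 0
#' @return distance in Angstrom
#' @export
#' @examples
#' minimum_image_distance(c(1, 0, 0), c(9, 0, 0), c(10, 10, 10)) # 2
minimum_image_distance <- function(p1, p2, box) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); box <- as.numeric(box)
  if (length(p1) != 3L || length(p2) != 3L) stop("positions must be length-3")
  if (!all(is.finite(p1)) || !all(is.finite(p2))) stop("non-finite coordinates")
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    stop("box components must be positive and finite")
  }
  d <- p1 - p2
  d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

# Vectorised minimum-image distances from one point to a matrix of points.
# Internal hot path for RDF and bond detection.
min_image_dist_to_many <- function(p, pts, box) {
  d <- sweep(pts, 2L, as.numeric(p), "-")
  d <- d - sweep(round(sweep(d, 2L, box, "/")), 2L, box, "*")
  sqrt(rowSums(d * d))
}

#' Select atoms by species and site name
#'
#' Returns the ordered atom indices matching the given species and site
#' labels. Passing several site names pools equivalent sites (e.g.
#' `c("O13", "O14")`, the two phosphoryl oxygens that share a negative
#' charge) into one population whose size is the pooled count; passing
#' several species unions them (e.g. the phosphorus atoms of both DOPC and
#' DOPS).
#'
#' @param system a `system_map`
#' @param species character vector of species labels
#' @param site_name character vector of site labels
#' @return integer vector of atom indices (ordered)
#' @export
select_sites <- function(system, species, site_name) {
  stopifnot(inherits(system, "system_map"))
  species <- as.character(species)
  site_name <- as.character(site_name)
  known_species <- unique(system$atoms$species)
  bad_sp <- setdiff(species, known_species)
  if (length(bad_sp) > 0L) {
    stop("unknown species: '", bad_sp[1], "'")
  }
  vocab <- unique(system$atoms$site_name[system$atoms$species %in% species])
  bad_site <- setdiff(site_name, vocab)
  if (length(bad_site) > 0L) {
    stop("unknown site '", bad_site[1], "' for species ",
         paste(species, collapse = "/"))
  }
  which(system$atoms$species %in% species & system$atoms$site_name %in% site_name)
}

#' Assign leaflets from phosphorus z-coordinates
#'
#' When a site map carries no leaflet labels they are computed from a
#' reference frame: a lipid is `"upper"` if its phosphorus z-coordinate lies
#' above the median z of all phosphorus atoms, `"lower"` otherwise.
#' Cholesterol (which has no phosphorus) is assigned by the same rule using
#' its hydroxyl oxygen. Drug, water and ion molecules get `"none"`.
#'
#' @param system a `system_map` (leaflet labels may be missing)
#' @param frame reference `md_frame` (typically frame 1)
#' @return a `system_map` with a complete leaflet assignment
#' @export
assign_leaflets <- function(system, frame) {
  stopifnot(inherits(system, "system_map"), inherits(frame, "md_frame"))
  at <- system$atoms
  z <- frame$positions[, 3]
  p_idx <- which(at$site_name == "P")
  if (length(p_idx) == 0L) stop("system has no phosphorus sites to split leaflets")
  z_med <- stats::median(z[p_idx])

  mol <- unique(at[, c("molecule_id", "species")])
  lab <- character(nrow(mol))
  for (i in seq_len(nrow(mol))) {
    sp <- mol$species[i]
    if (!sp %in% c("DOPC", "DOPS", "CHOL")) { lab[i] <- "none"; next }
    ref_site <- if (sp == "CHOL") "OH-O" else "P"
    j <- which(at$molecule_id == mol$molecule_id[i] & at$site_name == ref_site)
    if (length(j) == 0L) j <- which(at$molecule_id == mol$molecule_id[i])
    lab[i] <- if (mean(z[j]) > z_med) "upper" else "lower"
  }
  system_map(at, leaflet = data.frame(molecule_id = mol$molecule_id, leaflet = lab))
}
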