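# File readers and writers.
#
# Single frames: PDB (Angstrom; box in the CRYST1 record, read via bio3d)
# and GRO (nm; converted to Angstrom on ingest, box from the final line).
# Multi-frame series use the package's canonical plain-text trajectory
# format: per frame one header line "t Lx Ly Lz" followed by one "x y z"
# line per atom, all in ns / Angstrom. Site maps are JSON.

#' Read a PDB file as a frame
#'
#' Coordinates are taken from the ATOM/HETATM records (Angstrom); the box
#' comes from the CRYST1 record, which must describe an orthorhombic cell
#' (all angles 90 degrees) — triclinic cells are rejected.
#'
#' @param path PDB file path
#' @param time frame time in ns to stamp on the result (PDB carries none)
#' @return an `md_frame`
#' @export
read_pdb_frame <- function(path, time = 0) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  pos <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z)
  cl <- readLines(path)
  cl <- cl[startsWith(cl, "CRYST1")]
  if (length(cl) == 0L) stop("PDB file has no CRYST1 record: ", path)
  f <- strsplit(trimws(substring(cl[1], 7)), "\\s+")[[1]]
  abc <- as.numeric(f[1:3])
  ang <- as.numeric(f[4:6])
  if (any(abs(ang - 90) > 1e-3)) {
    stop("triclinic box in ", path, " (angles ", paste(ang, collapse = ", "),
         "); only orthorhombic boxes are supported")
  }
  md_frame(time, pos, abc)
}

#' Write a frame as a minimal PDB file
#'
#' @param frame an `md_frame`
#' @param system a `system_map` supplying species and site labels
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pdb_frame <- function(frame, system, path) {
  stopifnot(inherits(frame, "md_frame"), inherits(system, "system_map"))
  at <- system$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     frame$box[1], frame$box[2], frame$box[3], 90, 90, 90), con)
  p <- frame$positions
  for (i in seq_len(nrow(p))) {
    # residue name truncated to 4 chars, atom name to 4 — enough for the
    # site vocabulary used here
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
      i %% 100000L, substr(at$site_name[i], 1, 4), substr(at$species[i], 1, 4),
      at$molecule_id[i] %% 10000L, p[i, 1], p[i, 2], p[i, 3]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a GRO file as a frame
#'
#' GRO stores nm; coordinates and box are converted to Angstrom on ingest.
#' The final box line must have exactly three components (orthorhombic);
#' the nine-component triclinic form is rejected.
#'
#' @param path GRO file path
#' @param time frame time in ns
#' @return an `md_frame`
#' @export
read_gro_frame <- function(path, time = 0) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GRO file: ", path)
  n <- as.integer(trimws(lines[2]))
  if (is.na(n) || length(lines) < n + 3L) stop("truncated GRO file: ", path)
  atom_lines <- lines[3:(n + 2L)]
  # fixed columns: positions occupy chars 21-28, 29-36, 37-44 (nm, %8.3f)
  x <- as.numeric(substring(atom_lines, 21, 28))
  y <- as.numeric(substring(atom_lines, 29, 36))
  z <- as.numeric(substring(atom_lines, 37, 44))
  box <- as.numeric(strsplit(trimws(lines[n + 3L]), "\\s+")[[1]])
  if (length(box) != 3L) {
    stop("GRO box line has ", length(box),
         " components; only orthorhombic (3-component) boxes are supported")
  }
  md_frame(time, cbind(x, y, z) * 10, box * 10)
}

#' Write a frame as a GRO file (Angstrom converted to nm)
#'
#' @inheritParams write_pdb_frame
#' @return `path`, invisibly
#' @export
write_gro_frame <- function(frame, system, path) {
  stopifnot(inherits(frame, "md_frame"), inherits(system, "system_map"))
  at <- system$atoms
  p <- frame$positions / 10
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("memdrug frame t=%.6f ns", frame$time), con)
  writeLines(sprintf("%5d", nrow(p)), con)
  for (i in seq_len(nrow(p))) {
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       at$molecule_id[i] %% 100000L, substr(at$species[i], 1, 5),
                       substr(at$site_name[i], 1, 5), i %% 100000L,
                       p[i, 1], p[i, 2], p[i, 3]), con)
  }
  writeLines(sprintf("%10.5f%10.5f%10.5f", frame$box[1] / 10,
                     frame$box[2] / 10, frame$box[3] / 10), con)
  invisible(path)
}

#' Write a trajectory in the canonical plain-text format
#'
#' Per frame: one header line `t Lx Ly Lz` (ns, Angstrom) followed by one
#' `x y z` line per atom, repeated for every frame. The format is
#' self-describing given the atom count of the accompanying site map.
#'
#' @param traj an `md_trajectory`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    cat(sprintf("%.10g %.10g %.10g %.10g\n", f$time, f$box[1], f$box[2], f$box[3]),
        file = con)
    utils::write.table(format(f$positions, digits = 10, trim = TRUE,
                              scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a trajectory in the canonical plain-text format
#'
#' @param path trajectory file path
#' @param system the `system_map` the frames refer to (fixes the atom count)
#' @param dt optional sampling interval in ns; inferred from frame times if
#'   omitted
#' @return an `md_trajectory`
#' @export
read_trajectory <- function(path, system, dt = NULL) {
  stopifnot(inherits(system, "system_map"))
  na <- n_atoms(system)
  vals <- scan(path, what = numeric(), quiet = TRUE)
  per_frame <- 4L + 3L * na
  if (length(vals) %% per_frame != 0L) {
    stop("trajectory length is not a multiple of the frame record size (",
         per_frame, " numbers for ", na, " atoms)")
  }
  nf <- length(vals) %/% per_frame
  frames <- vector("list", nf)
  for (k in seq_len(nf)) {
    off <- (k - 1L) * per_frame
    hdr <- vals[off + 1:4]
    pos <- matrix(vals[off + 4L + seq_len(3L * na)], ncol = 3L, byrow = TRUE)
    frames[[k]] <- md_frame(hdr[1], pos, hdr[2:4])
  }
  md_trajectory(system, frames, dt = dt)
}

#' Write a site map as JSON
#'
#' The JSON layout is molecule-oriented: one record per molecule with its
#' species, leaflet label and named site -> atom-index map (1-based).
#'
#' @param system a `system_map`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_site_map <- function(system, path) {
  stopifnot(inherits(system, "system_map"))
  at <- system$atoms
  mol_ids <- unique(at$molecule_id)
  mols <- lapply(mol_ids, function(m) {
    rows <- which(at$molecule_id == m)
    sites <- as.list(rows)
    names(sites) <- at$site_name[rows]
    list(
      molecule_id = m,
      species = at$species[rows[1]],
      leaflet = system$leaflet$leaflet[match(m, system$leaflet$molecule_id)],
      sites = sites
    )
  })
  jsonlite::write_json(list(molecules = mols), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a site map from JSON
#'
#' @param path JSON site map path
#' @return a `system_map`
#' @export
read_site_map <- function(path) {
  j <- jsonlite::read_json(path)
  rows <- list()
  leaf <- list()
  for (m in j$molecules) {
    idx <- unlist(m$sites, use.names = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      atom_index = as.integer(idx),
      molecule_id = as.integer(m$molecule_id),
      species = as.character(m$species),
      site_name = names(idx),
      stringsAsFactors = FALSE
    )
    leaf[[length(leaf) + 1L]] <- data.frame(
      molecule_id = as.integer(m$molecule_id),
      leaflet = as.character(m$leaflet),
      stringsAsFactors = FALSE
    )
  }
  at <- do.call(rbind, rows)
  at <- at[order(at$atom_index), ]
  if (!identical(at$atom_index, seq_len(nrow(at)))) {
    stop("site map atom indices are not a contiguous 1..N sequence")
  }
  system_map(at[, c("molecule_id", "species", "site_name")],
             leaflet = do.call(rbind, leaf))
}

# CSV with a '#'-prefixed metadata header block (RFC-4180 body).
write_csv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]], digits = 12),
                                            collapse = " ")), con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_meta <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    k <- sub(":.*$", "", kv)
    v <- trimws(sub("^[^:]*:", "", kv))
    meta[[k]] <- v
  }
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  attr(df, "meta") <- meta
  df
}
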