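# Config-driven orchestration: membrane metrics, RDF battery, PMF barriers,
# lifetime table and bridge detection in one deterministic run with a
# provenance manifest.

.run_config_keys <- c(
  "trajectory", "site_map", "synthetic", "seed", "rdf_pairs",
  "pmf", "hbonds", "temperature", "output_dir"
)

#' Build and validate a run configuration
#'
#' Accepts a YAML file path or an equivalent nested list. Unknown top-level
#' keys are errors (fail-fast against typo-misconfiguration). The
#' configuration either names a trajectory + site-map file pair or carries
#' a `synthetic` block of [synthetic_config()] arguments; every referenced
#' species/site in the pair specs is resolved against the system before any
#' computation starts.
#'
#' Schema (top level): `trajectory` (path, optional), `site_map` (path,
#' required with `trajectory`), `synthetic` (list, optional), `seed`
#' (integer), `rdf_pairs` (list of `label`/`a`/`b` specs, where `a` and `b`
#' are `species`/`sites` lists; `r_max`/`delta_r` optional per pair),
#' `pmf` (`window`, `prominence`, `kcal_per_kbt`, `smooth_window`),
#' `hbonds` (`cutoff`, `tolerance`, `pairs` as in [pair_lifetime_table()],
#' `bridge_drug_sites`, `bridge_partners`), `temperature`, `output_dir`.
#'
#' @param config YAML path or list
#' @return a validated `run_config`
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .run_config_keys)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$trajectory) && is.null(config$synthetic)) {
    stop("configuration needs either 'trajectory' + 'site_map' or 'synthetic'")
  }
  if (!is.null(config$trajectory) && is.null(config$site_map)) {
    stop("'trajectory' requires a 'site_map'")
  }
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  config$temperature <- if (is.null(config$temperature)) 310.15 else as.numeric(config$temperature)
  # shallow default fill (modifyList would recurse into the pair lists)
  fill <- function(x, defaults) {
    if (is.null(x)) x <- list()
    for (k in names(defaults)) if (is.null(x[[k]])) x[[k]] <- defaults[[k]]
    x
  }
  config$pmf <- fill(config$pmf, list(window = c(1, 6), prominence = 0.05,
                                      kcal_per_kbt = 0.596))
  config$hbonds <- fill(config$hbonds, list(
    cutoff = 2.5, tolerance = 2, pairs = list(),
    bridge_drug_sites = c("H2", "H4"), bridge_partners = list()
  ))
  class(config) <- "run_config"
  config
}

resolve_trajectory <- function(config) {
  if (!is.null(config$trajectory)) {
    sys <- read_site_map(config$site_map)
    traj <- read_trajectory(config$trajectory, sys)
    list(trajectory = traj, timelines = NULL, source = "file")
  } else {
    syn_args <- config$synthetic
    syn_args$seed <- if (is.null(syn_args$seed)) config$seed else syn_args$seed
    cfg <- do.call(synthetic_config, syn_args)
    run <- generate_synthetic(cfg)
    list(trajectory = run$trajectory, timelines = run$timelines,
         source = "synthetic")
  }
}

# stable hash of the configuration for the manifest; the output directory
# is presentation, not analysis, so it does not enter the hash
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis battery
#'
#' Deterministic given (config, seed): membrane time series + summary, one
#' RDF/PMF/barrier per configured pair, the pooled-partner lifetime table,
#' bridge events, and a run manifest recording all parameters, the seed and
#' a config hash. Any stage error aborts with the stage name and the
#' offending pair label.
#'
#' @param config a `run_config` (or YAML path / list accepted by
#'   [run_config()])
#' @param output_dir output directory (created if missing); overrides the
#'   config's `output_dir`
#' @return invisibly, a list with the computed objects (`membrane`, `rdfs`,
#'   `pmfs`, `barriers`, `lifetimes`, `bridges`, `manifest`)
#' @export
run_all <- function(config, output_dir = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  out <- if (!is.null(output_dir)) output_dir else config$output_dir
  if (is.null(out)) stop("no output directory given")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, label, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "'",
           if (!is.null(label)) paste0(" [", label, "]") else "",
           " failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  src <- stage("input", NULL, resolve_trajectory(config))
  traj <- src$trajectory
  sys <- traj$system
  message("run_all: ", n_frames(traj), " frames, ", n_atoms(sys), " atoms (",
          src$source, " input)")

  # --- membrane metrics ---
  mem <- stage("membrane", NULL, membrane_series(traj))
  write_membrane_csv(mem, file.path(out, "membrane_timeseries.csv"),
                     file.path(out, "membrane_summary.json"))

  # --- RDF / PMF / barriers ---
  rdfs <- list(); pmfs <- list(); bar_rows <- list()
  for (ps in config$rdf_pairs) {
    lbl <- ps$label
    rdf <- stage("rdf", lbl, {
      sel_a <- select_sites(sys, ps$a$species, ps$a$sites)
      pooled_rdf(traj, sel_a, ps$b$species, ps$b$sites,
                 r_max = if (is.null(ps$r_max)) 12 else ps$r_max,
                 delta_r = if (is.null(ps$delta_r)) 0.05 else ps$delta_r)
    })
    rdfs[[lbl]] <- rdf
    write_rdf_csv(rdf, file.path(out, paste0("rdf_", sanitize_label(lbl), ".csv")))

    pmf <- stage("pmf", lbl, rdf_to_pmf(rdf, temperature = config$temperature))
    pmfs[[lbl]] <- pmf
    write_csv_meta(
      data.frame(r = pmf$r_centers,
                 W_kBT = ifelse(pmf$defined, pmf$W, NA_real_),
                 defined = pmf$defined),
      file.path(out, paste0("pmf_", sanitize_label(lbl), ".csv")),
      meta = list(temperature_K = pmf$temperature)
    )

    br <- stage("barrier", lbl, extract_barrier(
      pmf, window = as.numeric(config$pmf$window),
      prominence = config$pmf$prominence,
      smooth_window = config$pmf$smooth_window,
      kcal_per_kbt = config$pmf$kcal_per_kbt
    ))
    bar_rows[[lbl]] <- data.frame(
      pair_label = lbl, found = br$found,
      r_min = br$r_min, W_min = br$W_min, r_max = br$r_max, W_max = br$W_max,
      dW_kBT = br$delta_W, dW_kcal = br$delta_W_kcal,
      stringsAsFactors = FALSE
    )
  }
  barriers <- if (length(bar_rows) > 0L) do.call(rbind, bar_rows) else
    data.frame(pair_label = character(0), found = logical(0),
               r_min = numeric(0), W_min = numeric(0), r_max = numeric(0),
               W_max = numeric(0), dW_kBT = numeric(0), dW_kcal = numeric(0))
  write_csv_meta(barriers, file.path(out, "barriers.csv"),
                 meta = list(window = config$pmf$window,
                             prominence = config$pmf$prominence,
                             kcal_per_kbt = config$pmf$kcal_per_kbt))

  # --- hydrogen-bond lifetimes ---
  lt <- if (length(config$hbonds$pairs) > 0L) {
    stage("lifetimes", NULL, pair_lifetime_table(
      traj, config$hbonds$pairs,
      cutoff = config$hbonds$cutoff, tolerance = config$hbonds$tolerance
    ))
  } else {
    data.frame(pair_label = character(0), mean_distance_bound = numeric(0),
               tau = numeric(0), n_intervals = integer(0),
               bound_fraction = numeric(0), tolerance_used = numeric(0))
  }
  write_csv_meta(lt, file.path(out, "lifetimes.csv"),
                 meta = list(cutoff_A = config$hbonds$cutoff,
                             tolerance_ns = config$hbonds$tolerance))

  # --- bridges ---
  bridges <- if (length(config$hbonds$bridge_partners) > 0L) {
    stage("bridges", NULL, {
      drug_species <- unique(sys$atoms$species[grepl("^DBD", sys$atoms$species)])
      dsel <- select_sites(sys, drug_species, config$hbonds$bridge_drug_sites)
      psel <- unlist(lapply(config$hbonds$bridge_partners, function(bp) {
        select_sites(sys, bp$species, bp$sites)
      }))
      detect_bridges(traj, dsel, psel, cutoff = config$hbonds$cutoff)
    })
  } else {
    detect_bridges_empty()
  }
  write_csv_meta(bridges, file.path(out, "bridges.csv"),
                 meta = list(cutoff_A = config$hbonds$cutoff))

  # --- manifest ---
  manifest <- list(
    package = "memdrug",
    package_version = as.character(utils::packageVersion("memdrug")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "output_dir")],
    config_hash = config_hash(config),
    input_source = src$source,
    n_frames = n_frames(traj),
    n_atoms = n_atoms(sys),
    stages = c("membrane", "rdf", "pmf", "barrier", "lifetimes", "bridges")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(trajectory = traj, membrane = mem, rdfs = rdfs, pmfs = pmfs,
                 barriers = barriers, lifetimes = lt, bridges = bridges,
                 manifest = manifest, timelines = src$timelines))
}

sanitize_label <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

detect_bridges_empty <- function() {
  data.frame(
    frame = integer(0), time = numeric(0),
    drug_site_1 = character(0), drug_site_2 = character(0),
    partner_molecule_1 = integer(0), partner_species_1 = character(0),
    partner_site_1 = character(0),
    partner_molecule_2 = integer(0), partner_species_2 = character(0),
    partner_site_2 = character(0), stringsAsFactors = FALSE
  )
}

#' Default synthetic run configuration
#'
#' The pair battery analysed on the default synthetic system: the drug H2
#' site against the pooled DOPC phosphoryl oxygens O13/O14 (its configured
#' binding partner) and H4 against the cholesterol hydroxyl oxygen, for
#' RDF/PMF/barriers and lifetimes, plus bridge detection over both partner
#' pools.
#'
#' @param seed integer seed
#' @param n_frames,dt trajectory length settings forwarded to the
#'   synthetic block
#' @param output_dir output directory recorded in the config
#' @return a `run_config`
#' @export
default_synthetic_run_config <- function(seed = 1L, n_frames = 2000L,
                                         dt = 0.1, output_dir = "results") {
  run_config(list(
    synthetic = list(seed = seed, n_frames = n_frames, dt = dt),
    seed = seed,
    output_dir = output_dir,
    rdf_pairs = list(
      list(label = "H2 / O13-14 DOPC",
           a = list(species = "DBD3", sites = "H2"),
           b = list(species = "DOPC", sites = c("O13", "O14"))),
      list(label = "H4 / O Cholesterol",
           a = list(species = "DBD3", sites = "H4"),
           b = list(species = "CHOL", sites = "OH-O"))
    ),
    hbonds = list(
      pairs = list(
        list(label = "H2 / O13-14 DOPC",
             donor = list(species = "DBD3", site = "H2"),
             partner = list(species = "DOPC", sites = c("O13", "O14"))),
        list(label = "H4 / O Cholesterol",
             donor = list(species = "DBD3", site = "H4"),
             partner = list(species = "CHOL", sites = "OH-O"))
      ),
      bridge_partners = list(
        list(species = "DOPC", sites = c("O13", "O14")),
        list(species = "CHOL", sites = "OH-O")
      )
    )
  ))
}
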