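# Config-driven orchestration: one call runs hydrogen-bond detection,
# anomer preference, sliding-window RMSF and pathway/residency analysis on
# a trajectory (read from files or generated synthetically) and writes all
# CSV/JSON artifacts plus a checksummed manifest.

default_config <- function() {
  list(
    topology = NULL, trajectory = NULL, connectivity = NULL, synthetic = NULL,
    species_map = NULL, dt_ns = 0.1,
    membrane = list(z_center_A = NULL, half_thickness_A = 15, pore_radius_A = 10),
    hbond = list(d_max_A = 3.5, theta_min_deg = 150, stride = 1),
    thresholds = list(alpha_min_ratio = 1.4, beta_max_ratio = 0.7, min_total_bonds = 10),
    count = "bonds",
    rmsf = list(window_len_ns = 25, fit = TRUE, condition = ""),
    residency = list(gap_tolerance_ns = 0.5, min_duration_ns = 4, strict = TRUE),
    outdir = NULL, seed = 1)
}

merge_config <- function(user, defaults = default_config()) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]])) {
      defaults[[nm]] <- merge_config(user[[nm]], defaults[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load a run configuration
#'
#' @param config A YAML file path or a named list; unset keys take package
#'   defaults.
#' @return The merged configuration list.
#' @export
load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) config_error("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("config must be a list or a YAML file path")
  merge_config(config)
}

validate_config <- function(cfg) {
  if (is.null(cfg$species_map) || !length(cfg$species_map)) {
    config_error("config is missing the species name map (species_map)")
  }
  if (is.null(cfg$synthetic)) {
    if (is.null(cfg$topology) || is.null(cfg$trajectory)) {
      config_error("config needs either 'synthetic' or both 'topology' and 'trajectory'")
    }
    for (p in c(cfg$topology, cfg$trajectory, cfg$connectivity)) {
      if (!file.exists(p)) config_error("input file not found: ", p)
    }
  }
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Loads (or synthesises) a trajectory, tags ligand species, fixes the
#' membrane frame, then runs hydrogen-bond detection, the anomer
#' preference table with region summary, sliding-window RMSF, and ligand
#' pathway/residency analysis. If `outdir` is set, all artifacts are
#' written as CSV/JSON together with a run manifest that lists every
#' output file with its MD5 checksum; a fixed config and seed reproduce
#' the outputs byte for byte.
#'
#' @param config A config list or YAML path (see [load_config()]).
#' @return (Invisibly) a result bundle: trajectory, membrane, contact
#'   table, preference table, region summary, RMSF matrices, tracks,
#'   events, filtered events, transit summary, and written file list.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(load_config(config))
  ground_truth <- NULL
  if (!is.null(cfg$synthetic)) {
    if (!is.null(cfg$synthetic$propensities) &&
        !is.data.frame(cfg$synthetic$propensities)) {
      # YAML configs carry propensities as a list of records
      cfg$synthetic$propensities <-
        do.call(rbind, lapply(cfg$synthetic$propensities, as.data.frame))
    }
    spec <- do.call(synthetic_spec, c(cfg$synthetic, list(seed = cfg$seed)))
    sys <- build_toy_system(spec)
    ground_truth <- sys$ground_truth
    topo <- sys$topology
    traj <- simulate_flooding(topo, spec)
    cfg$dt_ns <- spec$dt_ns
    if (is.null(cfg$membrane$z_center_A)) cfg$membrane$z_center_A <- 0
    cfg$membrane$half_thickness_A <- spec$half_thickness_A
    cfg$membrane$pore_radius_A <- spec$pore_radius_A
  } else {
    topo <- read_topology(cfg$topology, cfg$connectivity)
    traj <- read_trajectory(topo, cfg$trajectory, dt_ns = cfg$dt_ns)
  }
  topo <- suppressMessages(tag_ligand_species(topo, unlist(cfg$species_map)))
  traj$topology <- topo

  membrane <- membrane_frame(
    traj, z_center_A = cfg$membrane$z_center_A,
    selection = cfg$membrane$selection,
    half_thickness_A = cfg$membrane$half_thickness_A,
    pore_axis_xy = cfg$membrane$pore_axis_xy,
    pore_radius_A = cfg$membrane$pore_radius_A)
  regions <- residue_regions(traj, membrane)

  criteria <- hbond_criteria(cfg$hbond$d_max_A, cfg$hbond$theta_min_deg)
  contacts <- hbond_timeseries(traj, criteria, stride = cfg$hbond$stride)

  thresholds <- preference_thresholds(cfg$thresholds$alpha_min_ratio,
                                      cfg$thresholds$beta_max_ratio,
                                      cfg$thresholds$min_total_bonds)
  pref <- withCallingHandlers(
    build_preference_table(contacts, regions, thresholds, count = cfg$count),
    warning = function(w) {
      message("preference: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  regsum <- region_summary(pref)

  ca <- which(topo$atoms$elety == "CA")
  rmsf_mats <- lapply(cfg$rmsf$window_len_ns, function(w) {
    suppressMessages(sliding_window_rmsf(traj, ca, w, fit = cfg$rmsf$fit,
                                         condition = cfg$rmsf$condition))
  })
  names(rmsf_mats) <- paste0("w", cfg$rmsf$window_len_ns)

  tracks <- ligand_tracks(traj, membrane)
  events <- detect_residency_events(
    tracks, membrane,
    contacts = if (cfg$hbond$stride == 1) contacts,
    regions = regions, gap_tolerance_ns = cfg$residency$gap_tolerance_ns)
  kept <- filter_events(events, cfg$residency$min_duration_ns, cfg$residency$strict)
  transit <- pore_transit_summary(kept, tracks)

  files <- character(0)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(cfg$outdir, name)
    write_contact_table(contacts, out("contact_table.csv"), out("hbond_events.csv"))
    utils::write.csv(pref, out("preference_table.csv"), row.names = FALSE)
    utils::write.csv(regsum, out("region_summary.csv"), row.names = FALSE)
    for (nm in names(rmsf_mats)) {
      write_rmsf_matrix(rmsf_mats[[nm]], out(paste0("rmsf_matrix_", nm, "ns.csv")))
    }
    utils::write.csv(as.data.frame(tracks), out("ligand_tracks.csv"), row.names = FALSE)
    utils::write.csv(kept, out("residency_events.csv"), row.names = FALSE)
    write_json_file(list(transit = transit,
                         exclusion = attr(kept, "exclusion_report")),
                    out("transit_summary.json"))
    if (!is.null(ground_truth)) write_ground_truth(ground_truth, out("ground_truth.json"))
    files <- setdiff(list.files(cfg$outdir, full.names = TRUE),
                     out("run_manifest.json"))
    manifest <- list(
      package = "anomertraj",
      version = as.character(utils::packageVersion("anomertraj")),
      seed = cfg$seed,
      parameters = list(hbond = cfg$hbond, thresholds = cfg$thresholds,
                        membrane = cfg$membrane[c("half_thickness_A", "pore_radius_A")],
                        z_center_A = membrane$z_center_A, count = cfg$count,
                        rmsf = cfg$rmsf, residency = cfg$residency, dt_ns = cfg$dt_ns),
      outputs = lapply(files, function(f) {
        list(file = basename(f), md5 = unname(tools::md5sum(f)))
      }))
    write_json_file(manifest, out("run_manifest.json"))
    files <- c(files, out("run_manifest.json"))
  }
  invisible(structure(list(
    config = cfg, trajectory = traj, membrane = membrane, regions = regions,
    contacts = contacts, preference = pref, region_summary = regsum,
    rmsf = rmsf_mats, tracks = tracks, events = events, filtered_events = kept,
    transit = transit, ground_truth = ground_truth, files = files),
    class = "anomertraj_run"))
}

#' Compare two pipeline runs (conditions)
#'
#' Produces the between-condition RMSF difference maps (first condition
#' minus second, per matching window length) and the per-residue bond-share
#' proportion shifts of each species, treating the first run as the mixed
#' condition and the second as the single-anomer reference.
#'
#' @param run_A,run_B Result bundles from [run_pipeline()] (or configs,
#'   which are run first). Systems must share residues and window grids.
#' @param species Species for the proportion shift (default: those present
#'   in both runs).
#' @param min_share_delta Flagging threshold for [proportion_shift()].
#' @param outdir Optional output directory for CSVs.
#' @return List of `RMSFDiffMap`s and proportion-shift tables.
#' @export
compare_conditions <- function(run_A, run_B, species = NULL,
                               min_share_delta = 0.02, outdir = NULL) {
  if (!inherits(run_A, "anomertraj_run")) run_A <- run_pipeline(run_A)
  if (!inherits(run_B, "anomertraj_run")) run_B <- run_pipeline(run_B)
  common <- intersect(names(run_A$rmsf), names(run_B$rmsf))
  diffs <- lapply(common, function(nm) {
    A <- run_A$rmsf[[nm]]; B <- run_B$rmsf[[nm]]
    if (!identical(rownames(A$values), rownames(B$values))) {
      mism <- c(setdiff(rownames(A$values), rownames(B$values)),
                setdiff(rownames(B$values), rownames(A$values)))
      data_error("incompatible residue sets: ", paste(mism, collapse = ", "))
    }
    rmsf_difference(A, B)
  })
  names(diffs) <- common
  if (is.null(species)) {
    species <- intersect(unique(run_A$contacts$counts$species),
                         unique(run_B$contacts$counts$species))
  }
  shifts <- lapply(species, function(s) {
    tryCatch(proportion_shift(run_A$contacts, run_B$contacts, s, min_share_delta),
             anomertraj_data_error = function(e) NULL)
  })
  names(shifts) <- species
  shifts <- Filter(Negate(is.null), shifts)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(diffs)) {
      write_rmsf_matrix(diffs[[nm]], file.path(outdir, paste0("rmsf_diff_", nm, "ns.csv")))
    }
    for (s in names(shifts)) {
      utils::write.csv(shifts[[s]], file.path(outdir, paste0("proportion_shift_", s, ".csv")),
                       row.names = FALSE)
    }
  }
  list(rmsf_diff = diffs, proportion_shifts = shifts)
}
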