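# Conditions with machine-readable classes so callers can distinguish
# configuration problems from malformed data.
config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("anomertraj_config_error", "error")))
}
data_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("anomertraj_data_error", "error")))
}

residue_key <- function(chain, resno) paste(chain, resno, sep = ":")

# Element symbol from a PDB atom-name string when the element column is blank.
element_from_name <- function(name) {
  stripped <- sub("^[0-9]+", "", name)
  toupper(substr(stripped, 1, 1))
}

new_topology <- function(atoms, xyz0, bonds = NULL) {
  stopifnot(is.data.frame(atoms), length(xyz0) == 3L * nrow(atoms))
  atoms$resid <- residue_key(atoms$chain, atoms$resno)
  residues <- unique(atoms[, c("resid", "resno", "resname", "chain")])
  rownames(residues) <- NULL
  has_ca <- tapply(atoms$elety == "CA", atoms$resid, any)
  residues$species <- ifelse(has_ca[residues$resid], "protein", "other")
  topo <- structure(
    list(atoms = atoms, xyz0 = as.numeric(xyz0), bonds = bonds,
         residues = residues, donors = NULL, acceptors = NULL),
    class = "Topology")
  derive_bond_roles(topo)
}

# Donors: N/O heavy atoms with >= 1 covalently attached hydrogen.
# Acceptors: all N/O heavy atoms. When no connectivity is available, each
# hydrogen is attached to the nearest heavy atom within 1.2 A in the
# reference coordinates; an orphan hydrogen is a tagging error.
derive_bond_roles <- function(topo) {
  atoms <- topo$atoms
  n <- nrow(atoms)
  heavy_no <- which(!atoms$is_hydrogen & atoms$element %in% c("N", "O"))
  h_idx <- which(atoms$is_hydrogen)
  coords <- matrix(topo$xyz0, ncol = 3, byrow = TRUE)

  h_parent <- integer(length(h_idx))
  if (length(h_idx)) {
    if (!is.null(topo$bonds)) {
      for (k in seq_along(h_idx)) {
        nb <- topo$bonds[[h_idx[k]]]
        nb <- nb[!atoms$is_hydrogen[nb]]
        if (!length(nb)) {
          data_error("hydrogen atom ", h_idx[k], " (", atoms$elety[h_idx[k]],
                     " in ", atoms$resid[h_idx[k]], ") has no bonded heavy atom")
        }
        h_parent[k] <- nb[1L]
      }
    } else {
      heavy_all <- which(!atoms$is_hydrogen)
      for (k in seq_along(h_idx)) {
        d2 <- colSums((t(coords[heavy_all, , drop = FALSE]) - coords[h_idx[k], ])^2)
        j <- which.min(d2)
        if (d2[j] > 1.2^2) {
          data_error("hydrogen atom ", h_idx[k], " (", atoms$elety[h_idx[k]],
                     " in ", atoms$resid[h_idx[k]],
                     ") has no heavy atom within 1.2 A and no connectivity was given")
        }
        h_parent[k] <- heavy_all[j]
      }
    }
  }
  keep <- h_parent %in% heavy_no
  donors <- data.frame(heavy = h_parent[keep], hydrogen = h_idx[keep])
  donors <- donors[order(donors$heavy, donors$hydrogen), , drop = FALSE]
  rownames(donors) <- NULL
  topo$donors <- donors
  topo$acceptors <- heavy_no
  topo
}

#' Read a topology from a PDB file
#'
#' Reads atoms (with residue identity and element) from a PDB file, taking
#' coordinates of the first model as the reference frame. Hydrogen-bond
#' donor and acceptor roles are derived immediately: if a PSF connectivity
#' file is supplied its bond list is used, otherwise each hydrogen is
#' attached to the nearest heavy atom within 1.2 Angstrom.
#'
#' @param path Path to a PDB file.
#' @param connectivity_path Optional path to a PSF file providing bonds.
#' @return A `Topology` object: atom table, reference coordinates, residue
#'   table with species tags (see [tag_ligand_species()]), and derived
#'   donor/acceptor sets.
#' @export
read_topology <- function(path, connectivity_path = NULL) {
  if (!file.exists(path)) data_error("cannot read topology file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) data_error("not a readable PDB file: ", path,
                                                 " (", conditionMessage(e), ")"))
  at <- pdb$atom
  element <- at$elesy
  blank <- is.na(element) | element == ""
  element[blank] <- element_from_name(at$elety[blank])
  element <- toupper(trimws(element))
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(
    eleno = seq_len(nrow(at)),
    elety = trimws(at$elety),
    element = element,
    resno = at$resno,
    resname = trimws(at$resid),
    chain = chain,
    is_hydrogen = element == "H",
    stringsAsFactors = FALSE)
  xyz0 <- as.numeric(pdb$xyz[1, ])
  bonds <- if (!is.null(connectivity_path)) read_psf_bonds(connectivity_path, nrow(atoms))
  new_topology(atoms, xyz0, bonds)
}

#' Tag ligand residues by species
#'
#' Assigns each residue whose name appears in `name_map` to its anomer
#' species; all remaining residues are tagged `protein` (if they contain a
#' CA atom) or `other`.
#'
#' @param topology A `Topology`.
#' @param name_map Named character vector mapping residue names to species,
#'   e.g. `c(GLC = "alpha", BGC = "beta")`.
#' @return The topology with updated residue species tags. The per-species
#'   ligand counts are reported via `message()`.
#' @export
tag_ligand_species <- function(topology, name_map) {
  if (length(name_map) == 0L) config_error("species name map is empty")
  if (is.null(names(name_map)) || any(names(name_map) == "")) {
    config_error("species name map must be a named vector (resname -> species)")
  }
  if (!all(name_map %in% c("alpha", "beta"))) {
    config_error("species must be 'alpha' or 'beta'; got: ",
                 paste(setdiff(name_map, c("alpha", "beta")), collapse = ", "))
  }
  dup <- duplicated(names(name_map))
  if (any(dup)) {
    clash <- tapply(name_map, names(name_map), function(v) length(unique(v)) > 1L)
    if (any(clash)) {
      config_error("residue name mapped to two species: ",
                   paste(names(clash)[clash], collapse = ", "))
    }
    name_map <- name_map[!dup]
  }
  res <- topology$residues
  has_ca <- tapply(topology$atoms$elety == "CA", topology$atoms$resid, any)
  res$species <- ifelse(has_ca[res$resid], "protein", "other")
  hit <- res$resname %in% names(name_map)
  res$species[hit] <- unname(name_map[res$resname[hit]])
  for (nm in names(name_map)) {
    if (!any(res$resname == nm)) {
      warning("species map name '", nm, "' matches no residue", call. = FALSE)
    }
  }
  topology$residues <- res
  counts <- table(factor(res$species, levels = c("alpha", "beta")))
  message("tagged ligands: ", counts[["alpha"]], " alpha, ", counts[["beta"]], " beta")
  topology
}

#' Read a coordinate trajectory
#'
#' Reads a multi-model PDB or a DCD file against an existing topology.
#' Frame times are assigned as `frame_index * dt_ns`; time metadata stored
#' inside trajectory files is deliberately ignored.
#'
#' @param topology A `Topology` with matching atom count.
#' @param path Path to a multi-model PDB (`.pdb`) or DCD (`.dcd`) file.
#' @param dt_ns Uniform frame spacing in nanoseconds.
#' @return A `Trajectory` object.
#' @export
read_trajectory <- function(topology, path, dt_ns = 0.1) {
  if (!file.exists(path)) data_error("cannot read trajectory file: ", path)
  ext <- tolower(tools::file_ext(path))
  xyz <- switch(ext,
    pdb = {
      pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                      error = function(e) data_error("not a readable PDB file: ", path))
      pdb$xyz
    },
    dcd = tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                   error = function(e) data_error("not a readable DCD file: ", path)),
    data_error("unsupported trajectory format: .", ext))
  xyz <- matrix(as.numeric(xyz), nrow = NROW(xyz))
  as_trajectory(topology, xyz, dt_ns)
}

#' Assemble a trajectory from in-memory coordinates
#'
#' @param topology A `Topology`.
#' @param xyz Numeric matrix, one row per frame, columns `x1,y1,z1,x2,...`
#'   (bio3d layout), in Angstrom.
#' @param dt_ns Uniform frame spacing in nanoseconds (> 0).
#' @return A `Trajectory`: the topology, the coordinate matrix, per-frame
#'   times in ns, and `dt_ns`.
#' @export
as_trajectory <- function(topology, xyz, dt_ns = 0.1) {
  if (!inherits(topology, "Topology")) config_error("topology must be a Topology")
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (nrow(xyz) == 0L) data_error("trajectory has zero frames")
  if (ncol(xyz) != 3L * nrow(topology$atoms)) {
    data_error("shape mismatch: trajectory has ", ncol(xyz) / 3,
               " atoms but topology has ", nrow(topology$atoms))
  }
  if (!all(is.finite(xyz))) data_error("trajectory contains non-finite coordinates")
  if (!(is.numeric(dt_ns) && length(dt_ns) == 1L && dt_ns > 0)) {
    config_error("dt_ns must be a single positive number")
  }
  structure(
    list(topology = topology, xyz = xyz, dt_ns = dt_ns,
         times_ns = (seq_len(nrow(xyz)) - 1L) * dt_ns),
    class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", nrow(x$xyz), "frames x", nrow(x$topology$atoms),
      "atoms, dt =", x$dt_ns, "ns, span =", nrow(x$xyz) * x$dt_ns, "ns\n")
  invisible(x)
}

#' Coordinates of one frame as an n x 3 matrix
#' @param trajectory A `Trajectory`.
#' @param i Frame index (1-based).
#' @export
frame_coords <- function(trajectory, i) {
  matrix(trajectory$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Define the membrane reference frame
#'
#' Fixes the z origin at the membrane centre (all downstream z values are
#' reported relative to it), the slab half thickness, and the pore axis.
#' The centre may be given explicitly or computed as the mean z of an atom
#' selection over the first frame (or averaged over all frames).
#'
#' @param trajectory A `Trajectory`.
#' @param z_center_A Explicit membrane-centre z in Angstrom, or `NULL` to
#'   compute it from `selection`.
#' @param selection Atom indices whose mean z defines the centre.
#' @param half_thickness_A Membrane half thickness in Angstrom.
#' @param pore_axis_xy Numeric length-2 (x, y) of the pore axis; default is
#'   the mean CA position of protein residues in the first frame.
#' @param pore_radius_A Pore radius in Angstrom.
#' @param average_frames If `TRUE`, average the selection z over all frames
#'   instead of using the first frame only.
#' @return A `MembraneFrame`.
#' @export
membrane_frame <- function(trajectory, z_center_A = NULL, selection = NULL,
                           half_thickness_A = 15, pore_axis_xy = NULL,
                           pore_radius_A = 10, average_frames = FALSE) {
  stopifnot(half_thickness_A > 0, pore_radius_A > 0)
  if (is.null(z_center_A)) {
    if (is.null(selection) || length(selection) == 0L) {
      data_error("empty selection: membrane centre needs z_center_A or atoms")
    }
    zcols <- 3L * selection
    z_center_A <- if (average_frames) mean(trajectory$xyz[, zcols]) else
      mean(trajectory$xyz[1L, zcols])
  }
  if (is.null(pore_axis_xy)) {
    topo <- trajectory$topology
    ca <- which(topo$atoms$elety == "CA")
    pore_axis_xy <- if (length(ca)) {
      c(mean(trajectory$xyz[1L, 3L * ca - 2L]), mean(trajectory$xyz[1L, 3L * ca - 1L]))
    } else c(0, 0)
  }
  structure(
    list(z_center_A = z_center_A, half_thickness_A = half_thickness_A,
         pore_axis_xy = as.numeric(pore_axis_xy), pore_radius_A = pore_radius_A),
    class = "MembraneFrame")
}
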