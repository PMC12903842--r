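# Synthetic toy-transporter "flooding" systems with known ground truth.
# A fixed pseudo-transporter of hydroxyl-bearing residues lines a vertical
# pore through an implicit membrane slab; two diffusing ligand species
# (alpha/beta glucose probes) form hydrogen bonds to residue r with exact
# per-frame probability p(r, s). Not a physical simulator: an oracle whose
# programmed propensities, regions, fluctuations and pathways the analysis
# stages must recover.

#' Specification of a synthetic flooding system
#'
#' @param n_ring_residues Residues per ring (z-level).
#' @param ring_levels_z z of each ring in Angstrom (membrane centre at 0).
#' @param ring_radius_A Radius of the CA ring (Angstrom).
#' @param half_thickness_A Membrane slab half thickness (Angstrom).
#' @param pore_radius_A Pore radius (Angstrom).
#' @param n_ligands_alpha,n_ligands_beta Ligand copies per species.
#' @param propensities Data frame `resno`, `p_alpha`, `p_beta`: per-frame
#'   hydrogen-bond probability of that residue to each species. Residues
#'   not listed have propensity 0.
#' @param sigma_step_A Ligand random-walk step s.d. per axis per frame.
#' @param sigma_res_A Residue thermal jitter s.d. per axis (so the
#'   ground-truth CA RMSF is `sigma_res_A * sqrt(3)`).
#' @param paths Optional programmed permeation paths: list of
#'   `list(species =, copy =, waypoints = data.frame(frame, x, y, z))`;
#'   waypoints are linearly interpolated and the ligand follows them
#'   instead of diffusing.
#' @param n_frames Number of frames.
#' @param dt_ns Frame spacing (ns).
#' @param box_xy_A,box_z_A Reflecting half-widths of the ligand box.
#' @param seed Integer seed; fixed seed gives byte-identical output files.
#' @export
synthetic_spec <- function(n_ring_residues = 6L,
                           ring_levels_z = c(-20, -7.5, 7.5, 20),
                           ring_radius_A = 8,
                           half_thickness_A = 15,
                           pore_radius_A = 10,
                           n_ligands_alpha = 10L,
                           n_ligands_beta = 10L,
                           propensities = NULL,
                           sigma_step_A = 1.0,
                           sigma_res_A = 0.3,
                           paths = NULL,
                           n_frames = 5000L,
                           dt_ns = 0.1,
                           box_xy_A = 30,
                           box_z_A = 35,
                           seed = 1L) {
  check_pos <- function(x, nm) if (!(is.numeric(x) && length(x) == 1L && x > 0)) {
    config_error("invalid synthetic spec field '", nm, "': must be a positive number")
  }
  check_pos(n_ring_residues, "n_ring_residues")
  check_pos(ring_radius_A, "ring_radius_A")
  check_pos(half_thickness_A, "half_thickness_A")
  check_pos(pore_radius_A, "pore_radius_A")
  check_pos(sigma_step_A, "sigma_step_A")
  check_pos(sigma_res_A, "sigma_res_A")
  check_pos(n_frames, "n_frames")
  check_pos(dt_ns, "dt_ns")
  check_pos(box_xy_A, "box_xy_A")
  check_pos(box_z_A, "box_z_A")
  if (n_ligands_alpha < 0 || n_ligands_beta < 0) {
    config_error("invalid synthetic spec field 'n_ligands': must be >= 0")
  }
  if (!length(ring_levels_z)) config_error("invalid synthetic spec field 'ring_levels_z'")
  n_res <- n_ring_residues * length(ring_levels_z)
  if (is.null(propensities)) {
    propensities <- data.frame(resno = integer(0), p_alpha = numeric(0),
                               p_beta = numeric(0))
  }
  stopifnot(all(c("resno", "p_alpha", "p_beta") %in% names(propensities)))
  if (any(propensities$p_alpha < 0 | propensities$p_alpha > 1 |
          propensities$p_beta < 0 | propensities$p_beta > 1)) {
    config_error("invalid synthetic spec field 'propensities': values must be in [0, 1]")
  }
  if (any(propensities$resno < 1L | propensities$resno > n_res)) {
    config_error("invalid synthetic spec field 'propensities': resno outside 1..", n_res)
  }
  structure(
    list(n_ring_residues = as.integer(n_ring_residues),
         ring_levels_z = as.numeric(ring_levels_z),
         ring_radius_A = ring_radius_A, half_thickness_A = half_thickness_A,
         pore_radius_A = pore_radius_A,
         n_ligands_alpha = as.integer(n_ligands_alpha),
         n_ligands_beta = as.integer(n_ligands_beta),
         propensities = propensities, sigma_step_A = sigma_step_A,
         sigma_res_A = sigma_res_A, paths = paths,
         n_frames = as.integer(n_frames), dt_ns = dt_ns,
         box_xy_A = box_xy_A, box_z_A = box_z_A, seed = as.integer(seed)),
    class = "SyntheticSpec")
}

# Linear interpolation of programmed waypoints onto every frame; the path
# holds its first/last waypoint outside the waypoint range.
interpolate_path <- function(waypoints, n_frames) {
  f <- seq_len(n_frames)
  cbind(stats::approx(waypoints$frame, waypoints$x, xout = f, rule = 2)$y,
        stats::approx(waypoints$frame, waypoints$y, xout = f, rule = 2)$y,
        stats::approx(waypoints$frame, waypoints$z, xout = f, rule = 2)$y)
}

#' Build the toy transporter topology and its ground truth
#'
#' The pseudo-protein is a stack of rings of serine-like three-atom
#' residues (CA; a hydroxyl oxygen OG offset toward the pore axis, which
#' is both hydrogen-bond donor and acceptor; its hydrogen HG pointing
#' tangentially). Ligands are two-atom hydroxyl probes (O1-H1) with
#' residue names GLC (alpha) / BGC (beta), parked in the reservoirs above
#' and below the slab.
#'
#' @param spec A [synthetic_spec()].
#' @return `list(topology =, ground_truth =)`. The ground truth holds each
#'   residue's true propensities and ratio, its membrane region, the
#'   ligand assignment used for bond placement, programmed residency
#'   events implied by the paths, and the expected CA RMSF.
#' @export
build_toy_system <- function(spec) {
  nr <- spec$n_ring_residues
  levels_z <- spec$ring_levels_z
  n_res <- nr * length(levels_z)
  rows <- list()
  coords <- list()
  resno <- 0L
  for (z in levels_z) {
    for (i in seq_len(nr)) {
      resno <- resno + 1L
      th <- 2 * pi * (i - 1) / nr
      radial <- c(cos(th), sin(th), 0)
      tangent <- c(-sin(th), cos(th), 0)
      ca <- spec$ring_radius_A * radial + c(0, 0, z)
      og <- (spec$ring_radius_A - 1.5) * radial + c(0, 0, z)
      hg <- og + 0.96 * tangent
      rows[[resno]] <- data.frame(
        elety = c("CA", "OG", "HG"), element = c("C", "O", "H"),
        resno = resno, resname = "SER", chain = "A",
        is_hydrogen = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
      coords[[resno]] <- rbind(ca, og, hg)
    }
  }
  # reservoir ligands, deterministic staggered placement
  lig_row <- function(resno, resname, pos) {
    list(atoms = data.frame(elety = c("O1", "H1"), element = c("O", "H"),
                            resno = resno, resname = resname, chain = "L",
                            is_hydrogen = c(FALSE, TRUE), stringsAsFactors = FALSE),
         coords = rbind(pos, pos + c(0.96, 0, 0)))
  }
  res_rad <- min(spec$box_xy_A - 5, spec$ring_radius_A + 8)
  lig_z <- spec$half_thickness_A + 8
  k <- 0L
  for (s in c("alpha", "beta")) {
    n_l <- if (s == "alpha") spec$n_ligands_alpha else spec$n_ligands_beta
    resname <- if (s == "alpha") "GLC" else "BGC"
    for (j in seq_len(n_l)) {
      k <- k + 1L
      th <- 2 * pi * (k - 1) / max(1L, spec$n_ligands_alpha + spec$n_ligands_beta)
      side <- if (j %% 2L == 1L) 1 else -1
      pos <- c(res_rad * cos(th), res_rad * sin(th), side * lig_z)
      lr <- lig_row(100L + k, resname, pos)
      rows[[n_res + k]] <- lr$atoms
      coords[[n_res + k]] <- lr$coords
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  xyz0 <- as.vector(t(do.call(rbind, coords)))
  # explicit connectivity: CA-OG and OG-HG per residue, O1-H1 per ligand
  bonds <- vector("list", nrow(atoms))
  for (r in seq_len(n_res)) {
    b <- 3L * (r - 1L)
    bonds[[b + 1L]] <- b + 2L
    bonds[[b + 2L]] <- c(b + 1L, b + 3L)
    bonds[[b + 3L]] <- b + 2L
  }
  n_lig <- spec$n_ligands_alpha + spec$n_ligands_beta
  for (l in seq_len(n_lig)) {
    b <- 3L * n_res + 2L * (l - 1L)
    bonds[[b + 1L]] <- b + 2L
    bonds[[b + 2L]] <- b + 1L
  }
  topo <- new_topology(atoms, xyz0, bonds)
  topo <- suppressMessages(tag_ligand_species(topo, c(GLC = "alpha", BGC = "beta")))

  membrane <- structure(
    list(z_center_A = 0, half_thickness_A = spec$half_thickness_A,
         pore_axis_xy = c(0, 0), pore_radius_A = spec$pore_radius_A),
    class = "MembraneFrame")
  z_res <- rep(levels_z, each = nr)
  region <- assign_region(z_res, rep(spec$ring_radius_A, n_res), membrane)
  p <- merge(data.frame(resno = seq_len(n_res)), spec$propensities,
             by = "resno", all.x = TRUE)
  p$p_alpha[is.na(p$p_alpha)] <- 0
  p$p_beta[is.na(p$p_beta)] <- 0
  gt_res <- data.frame(
    resid = residue_key("A", seq_len(n_res)), resno = seq_len(n_res),
    p_alpha = p$p_alpha, p_beta = p$p_beta,
    rho = ifelse(p$p_beta > 0, p$p_alpha / p$p_beta, Inf),
    region = region, stringsAsFactors = FALSE)

  gt <- list(residues = gt_res, membrane = membrane,
             sigma_res_A = spec$sigma_res_A,
             rmsf_expected_A = spec$sigma_res_A * sqrt(3),
             ligand_map = assign_bond_ligands(spec),
             programmed_events = programmed_pore_events(spec, membrane),
             rng = "R default (Mersenne-Twister), one stream seeded once; per frame: residue jitter block, walker steps in ligand order, bond draws by (resno; alpha then beta)",
             spec = spec)
  list(topology = topo, ground_truth = gt)
}

# Which ligand copy serves which biased (residue, species): biased residues
# in resno order map one-to-one onto that species' non-programmed copies,
# cycling when outnumbered (then simultaneous draws can collide and the
# later residue wins; warned at simulation time).
assign_bond_ligands <- function(spec) {
  path_copies <- list(alpha = integer(0), beta = integer(0))
  for (p in spec$paths) path_copies[[p$species]] <- c(path_copies[[p$species]], p$copy)
  out <- list()
  for (s in c("alpha", "beta")) {
    p_col <- if (s == "alpha") "p_alpha" else "p_beta"
    biased <- spec$propensities$resno[spec$propensities[[p_col]] > 0]
    if (!length(biased)) next
    n_l <- if (s == "alpha") spec$n_ligands_alpha else spec$n_ligands_beta
    free <- setdiff(seq_len(n_l), path_copies[[s]])
    if (!length(free)) config_error("no free ", s, " ligand copies for bond placement")
    copy <- free[(seq_along(biased) - 1L) %% length(free) + 1L]
    out[[s]] <- data.frame(species = s, resno = sort(biased), copy = copy)
  }
  if (!length(out)) {
    return(data.frame(species = character(0), resno = integer(0), copy = integer(0)))
  }
  do.call(rbind, out)
}

# Residency events implied by the programmed paths (gap tolerance 0),
# reported in frames so recovery can be checked to within one frame.
programmed_pore_events <- function(spec, membrane) {
  out <- list()
  for (p in spec$paths) {
    path <- interpolate_path(p$waypoints, spec$n_frames)
    in_pore <- abs(path[, 3]) <= membrane$half_thickness_A &
      sqrt(path[, 1]^2 + path[, 2]^2) <= membrane$pore_radius_A
    seg <- runs_with_merge(in_pore, 0L)
    if (!nrow(seg)) next
    out[[length(out) + 1L]] <- data.frame(
      species = p$species, copy = p$copy, start_frame = seg[, 1],
      end_frame = seg[, 2], duration_ns = (seg[, 2] - seg[, 1] + 1L) * spec$dt_ns,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(species = character(0), copy = integer(0),
                      start_frame = integer(0), end_frame = integer(0),
                      duration_ns = numeric(0)))
  }
  do.call(rbind, out)
}

#' Simulate a synthetic flooding trajectory
#'
#' Per frame: (1) every residue jitters rigidly with isotropic Gaussian
#' noise `sigma_res_A`; (2) each free ligand takes a Gaussian random-walk
#' step inside a reflecting box (programmed-path ligands follow their
#' interpolated waypoints instead) and is then pushed back to a 5 Angstrom
#' clearance from all protein N/O so no accidental hydrogen bond can
#' occur; (3) with probability `p(r, s)` the ligand assigned to a biased
#' (residue, species) pair is snapped into ideal hydrogen-bond geometry
#' (O...O 2.9 Angstrom, D-H...A 180 degrees), guaranteeing detection at
#' default criteria, so ground-truth propensities translate exactly into
#' detection probabilities.
#'
#' One RNG stream is seeded once from `spec$seed` and consumed in a fixed
#' documented order, so a fixed spec yields byte-identical trajectories.
#'
#' @param topology Topology from [build_toy_system()] with the same spec.
#' @param spec The [synthetic_spec()].
#' @return A `Trajectory`.
#' @export
simulate_flooding <- function(topology, spec) {
  n_res <- spec$n_ring_residues * length(spec$ring_levels_z)
  n_lig <- spec$n_ligands_alpha + spec$n_ligands_beta
  n_atoms <- nrow(topology$atoms)
  if (n_atoms != 3L * n_res + 2L * n_lig) {
    config_error("topology does not match spec (atom count ", n_atoms,
                 " vs expected ", 3L * n_res + 2L * n_lig, ")")
  }
  base <- matrix(topology$xyz0, ncol = 3, byrow = TRUE)
  prot_atoms <- seq_len(3L * n_res)
  res_of_prot_atom <- rep(seq_len(n_res), each = 3L)
  og_idx <- 3L * seq_len(n_res) - 1L
  prot_no <- which(!topology$atoms$is_hydrogen[prot_atoms] &
                   topology$atoms$element[prot_atoms] %in% c("N", "O"))
  lig_o <- 3L * n_res + 2L * seq_len(n_lig) - 1L
  lig_h <- lig_o + 1L

  # ligand bookkeeping: global copy index = alpha copies then beta copies
  copy_global <- function(species, copy) if (species == "alpha") copy else
    spec$n_ligands_alpha + copy
  path_xyz <- list()
  for (p in spec$paths) {
    path_xyz[[as.character(copy_global(p$species, p$copy))]] <-
      interpolate_path(p$waypoints, spec$n_frames)
  }
  is_walker <- !(as.character(seq_len(n_lig)) %in% names(path_xyz))
  lig_map <- assign_bond_ligands(spec)
  if (nrow(lig_map) && anyDuplicated(lig_map[, c("species", "copy")])) {
    warning("more biased residues than ligand copies: simultaneous bond draws ",
            "on a shared copy collide (the later residue wins)", call. = FALSE)
  }
  # draw order: residues ascending, alpha before beta within a residue
  draws <- spec$propensities[order(spec$propensities$resno), , drop = FALSE]
  draw_list <- list()
  for (i in seq_len(nrow(draws))) {
    for (s in c("alpha", "beta")) {
      p <- if (s == "alpha") draws$p_alpha[i] else draws$p_beta[i]
      if (p > 0) {
        m <- lig_map[lig_map$species == s & lig_map$resno == draws$resno[i], ]
        draw_list[[length(draw_list) + 1L]] <- list(
          resno = draws$resno[i], p = p,
          lig = copy_global(s, m$copy[1L]))
      }
    }
  }

  set.seed(spec$seed)
  xyz <- matrix(0, spec$n_frames, 3L * n_atoms)
  lig_pos <- base[lig_o, , drop = FALSE]  # walker state (O atom)
  clearance <- 5.0
  reflect <- function(v, lim) {
    v <- ((v + lim) %% (4 * lim))
    ifelse(v > 2 * lim, 4 * lim - v, v) - lim
  }
  for (f in seq_len(spec$n_frames)) {
    jitter <- matrix(stats::rnorm(3L * n_res, sd = spec$sigma_res_A), n_res, 3L)
    prot <- base[prot_atoms, , drop = FALSE] + jitter[res_of_prot_atom, , drop = FALSE]
    n_walk <- sum(is_walker)
    if (n_walk) {
      steps <- matrix(stats::rnorm(3L * n_walk, sd = spec$sigma_step_A), n_walk, 3L,
                      byrow = TRUE)
      lig_pos[is_walker, ] <- lig_pos[is_walker, , drop = FALSE] + steps
      lig_pos[is_walker, 1] <- reflect(lig_pos[is_walker, 1], spec$box_xy_A)
      lig_pos[is_walker, 2] <- reflect(lig_pos[is_walker, 2], spec$box_xy_A)
      lig_pos[is_walker, 3] <- reflect(lig_pos[is_walker, 3], spec$box_z_A)
    }
    frame_lig <- lig_pos
    for (g in which(!is_walker)) frame_lig[g, ] <- path_xyz[[as.character(g)]][f, ]
    # clearance: keep free ligands out of hydrogen-bond range of protein N/O
    pno <- prot[prot_no, , drop = FALSE]
    for (g in which(is_walker)) {
      dvec <- t(pno) - frame_lig[g, ]
      d2 <- colSums(dvec * dvec)
      j <- which.min(d2)
      if (d2[j] < clearance^2) {
        d <- sqrt(d2[j])
        away <- if (d > 1e-9) -dvec[, j] / d else c(1, 0, 0)
        frame_lig[g, ] <- pno[j, ] + clearance * away
        lig_pos[g, ] <- frame_lig[g, ]
      }
    }
    lig_hpos <- frame_lig + matrix(c(0.96, 0, 0), n_lig, 3L, byrow = TRUE)
    # bond draws: snap assigned ligand into ideal geometry
    for (d in draw_list) {
      if (stats::runif(1L) < d$p) {
        og <- prot[og_idx[d$resno], ]
        to_axis <- c(-og[1], -og[2], 0)
        dir <- to_axis / sqrt(sum(to_axis^2))
        if (d$lig > spec$n_ligands_alpha) {
          # rotate the beta approach 20 degrees toward the HG side so
          # simultaneous alpha/beta bonds to one residue never overlap
          th0 <- atan2(dir[2], dir[1]) + 20 * pi / 180
          dir <- c(cos(th0), sin(th0), 0)
        }
        o_new <- og + 2.9 * dir
        frame_lig[d$lig, ] <- o_new
        lig_hpos[d$lig, ] <- o_new - 0.96 * dir
      }
    }
    row <- numeric(3L * n_atoms)
    row[as.vector(t(cbind(3L * prot_atoms - 2L, 3L * prot_atoms - 1L, 3L * prot_atoms)))] <-
      as.vector(t(prot))
    row[as.vector(t(cbind(3L * lig_o - 2L, 3L * lig_o - 1L, 3L * lig_o)))] <-
      as.vector(t(frame_lig))
    row[as.vector(t(cbind(3L * lig_h - 2L, 3L * lig_h - 1L, 3L * lig_h)))] <-
      as.vector(t(lig_hpos))
    xyz[f, ] <- row
  }
  as_trajectory(topology, xyz, spec$dt_ns)
}

#' Write the ground truth of a synthetic system as JSON
#' @param ground_truth The `ground_truth` element from [build_toy_system()].
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- ground_truth
  gt$membrane <- unclass(gt$membrane)
  gt$residues$rho[!is.finite(gt$residues$rho)] <- "inf"
  write_json_file(gt[c("residues", "membrane", "sigma_res_A", "rmsf_expected_A",
                       "ligand_map", "programmed_events", "rng")], path)
}
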