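# Geometric hydrogen-bond detection between ligand species and protein
# residues. A bond is scored on the donor--acceptor heavy-atom distance and
# the D-H...A angle measured at the hydrogen. The criteria are a declared
# convention (configurable), surfaced in every output.

#' Hydrogen-bond geometric criteria
#'
#' @param d_max_A Maximum donor--acceptor heavy-atom distance (Angstrom,
#'   default 3.5, must be <= 5).
#' @param theta_min_deg Minimum donor-hydrogen-acceptor angle at the
#'   hydrogen (degrees, default 150, must be >= 90).
#' @export
hbond_criteria <- function(d_max_A = 3.5, theta_min_deg = 150) {
  if (!(d_max_A > 0 && d_max_A <= 5.0)) {
    config_error("d_max_A must be in (0, 5] Angstrom, got ", d_max_A)
  }
  if (!(theta_min_deg >= 90 && theta_min_deg <= 180)) {
    config_error("theta_min_deg must be in [90, 180] degrees, got ", theta_min_deg)
  }
  structure(list(d_max_A = d_max_A, theta_min_deg = theta_min_deg),
            class = "HBondCriteria")
}

# Candidate (donor, hydrogen, acceptor) triples with exactly one ligand side
# and one protein side; intra-protein and ligand-ligand pairs are excluded
# up front. Computed once per topology and reused across frames.
hbond_candidates <- function(topology) {
  atoms <- topology$atoms
  res <- topology$residues
  species_of <- res$species[match(atoms$resid, res$resid)]
  don <- topology$donors
  acc <- topology$acceptors
  if (nrow(don) == 0L || length(acc) == 0L) {
    return(data.frame(D = integer(0), H = integer(0), A = integer(0),
                      species = character(0), ligand_resid = character(0),
                      protein_resid = character(0), ligand_resno = integer(0),
                      protein_resno = integer(0)))
  }
  grid <- expand.grid(d = seq_len(nrow(don)), a = seq_along(acc))
  D <- don$heavy[grid$d]; H <- don$hydrogen[grid$d]; A <- acc[grid$a]
  sd <- species_of[D]; sa <- species_of[A]
  lig <- c("alpha", "beta")
  d_is_lig <- sd %in% lig
  a_is_lig <- sa %in% lig
  keep <- D != A & ((d_is_lig & sa == "protein") | (sd == "protein" & a_is_lig))
  D <- D[keep]; H <- H[keep]; A <- A[keep]
  d_is_lig <- d_is_lig[keep]
  lig_atom <- ifelse(d_is_lig, D, A)
  prot_atom <- ifelse(d_is_lig, A, D)
  data.frame(
    D = D, H = H, A = A,
    species = species_of[lig_atom],
    ligand_resid = atoms$resid[lig_atom],
    protein_resid = atoms$resid[prot_atom],
    ligand_resno = atoms$resno[lig_atom],
    protein_resno = atoms$resno[prot_atom],
    stringsAsFactors = FALSE)
}

as_coord_matrix <- function(frame) {
  if (is.matrix(frame)) frame else matrix(frame, ncol = 3, byrow = TRUE)
}

hbond_event_frame <- function(cand, idx, dist, ang) {
  data.frame(
    donor_atom = cand$D[idx], hydrogen_atom = cand$H[idx], acceptor_atom = cand$A[idx],
    distance_A = dist, angle_deg = ang,
    ligand_resid = cand$ligand_resid[idx], ligand_resno = cand$ligand_resno[idx],
    protein_resid = cand$protein_resid[idx], protein_resno = cand$protein_resno[idx],
    species = cand$species[idx],
    stringsAsFactors = FALSE)
}

#' Detect ligand--protein hydrogen bonds in one frame
#'
#' Returns every ligand-to-protein and protein-to-ligand
#' donor--hydrogen--acceptor triple with heavy-atom distance `<= d_max_A`
#' and D-H...A angle `>= theta_min_deg`. Intra-protein and ligand--ligand
#' contacts are never reported.
#'
#' @param frame An n x 3 coordinate matrix or flat `x1,y1,z1,...` vector.
#' @param topology A `Topology` with derived donor/acceptor sets.
#' @param criteria An [hbond_criteria()] object.
#' @param candidates Precomputed candidate triples (internal reuse).
#' @return Data frame of events (one row per bond) with geometry, residue
#'   identifiers and species.
#' @export
detect_hbonds <- function(frame, topology, criteria = hbond_criteria(),
                          candidates = NULL) {
  coords <- as_coord_matrix(frame)
  cand <- if (is.null(candidates)) hbond_candidates(topology) else candidates
  if (nrow(cand) == 0L) return(hbond_event_frame(cand, integer(0), numeric(0), numeric(0)))
  dd <- coords[cand$D, , drop = FALSE] - coords[cand$A, , drop = FALSE]
  d2 <- rowSums(dd * dd)
  near <- which(d2 <= criteria$d_max_A^2)
  if (!length(near)) return(hbond_event_frame(cand, integer(0), numeric(0), numeric(0)))
  v1 <- coords[cand$D[near], , drop = FALSE] - coords[cand$H[near], , drop = FALSE]
  v2 <- coords[cand$A[near], , drop = FALSE] - coords[cand$H[near], , drop = FALSE]
  cosang <- rowSums(v1 * v2) / (sqrt(rowSums(v1 * v1)) * sqrt(rowSums(v2 * v2)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ok <- ang >= criteria$theta_min_deg
  hbond_event_frame(cand, near[ok], sqrt(d2[near[ok]]), ang[ok])
}

#' Exhaustive brute-force hydrogen-bond detection (test oracle)
#'
#' Enumerates every (donor, hydrogen, acceptor) triple with scalar
#' arithmetic and applies the same geometric predicate as
#' [detect_hbonds()]. Intended as ground truth in tests; refuses frames
#' above 1000 atoms.
#'
#' @inheritParams detect_hbonds
#' @export
oracle_detect_hbonds <- function(frame, topology, criteria = hbond_criteria()) {
  coords <- as_coord_matrix(frame)
  if (nrow(coords) > 1000L) data_error("oracle limited to frames of <= 1000 atoms")
  atoms <- topology$atoms
  res <- topology$residues
  species_of <- res$species[match(atoms$resid, res$resid)]
  out <- list()
  k <- 0L
  for (di in seq_len(nrow(topology$donors))) {
    D <- topology$donors$heavy[di]
    H <- topology$donors$hydrogen[di]
    for (A in topology$acceptors) {
      if (A == D) next
      sd <- species_of[D]; sa <- species_of[A]
      lig_d <- sd %in% c("alpha", "beta"); lig_a <- sa %in% c("alpha", "beta")
      if (!((lig_d && sa == "protein") || (sd == "protein" && lig_a))) next
      dvec <- coords[D, ] - coords[A, ]
      dist <- sqrt(sum(dvec^2))
      if (dist > criteria$d_max_A) next
      v1 <- coords[D, ] - coords[H, ]
      v2 <- coords[A, ] - coords[H, ]
      cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
      ang <- acos(min(max(cosang, -1), 1)) * 180 / pi
      if (ang < criteria$theta_min_deg) next
      lig_atom <- if (lig_d) D else A
      prot_atom <- if (lig_d) A else D
      k <- k + 1L
      out[[k]] <- data.frame(
        donor_atom = D, hydrogen_atom = H, acceptor_atom = A,
        distance_A = dist, angle_deg = ang,
        ligand_resid = atoms$resid[lig_atom], ligand_resno = atoms$resno[lig_atom],
        protein_resid = atoms$resid[prot_atom], protein_resno = atoms$resno[prot_atom],
        species = species_of[lig_atom],
        stringsAsFactors = FALSE)
    }
  }
  if (!k) {
    cand0 <- data.frame(D = integer(0), H = integer(0), A = integer(0),
                        species = character(0), ligand_resid = character(0),
                        protein_resid = character(0), ligand_resno = integer(0),
                        protein_resno = integer(0))
    return(hbond_event_frame(cand0, integer(0), numeric(0), numeric(0)))
  }
  do.call(rbind, out)
}

#' Per-frame hydrogen-bond time series and contact table
#'
#' Runs [detect_hbonds()] over every `stride`-th frame and aggregates
#' bond-frame counts and per-frame presence per (protein residue, species).
#' A residue holding two simultaneous bonds to one ligand in one frame
#' contributes 2 to its bond-frame count `n_bonds` but only 1 to
#' `frames_present`.
#'
#' @param trajectory A `Trajectory`.
#' @param criteria An [hbond_criteria()] object.
#' @param stride Analyse every `stride`-th frame (>= 1, < frame count).
#' @param chunk_frames Internal vectorisation block size.
#' @return A `ContactTable`: `counts` (per residue x species), the full
#'   `events` data frame, scanned frame indices, and the criteria used.
#' @export
hbond_timeseries <- function(trajectory, criteria = hbond_criteria(), stride = 1L,
                             chunk_frames = 1000L) {
  n_frames <- nrow(trajectory$xyz)
  if (n_frames == 0L) data_error("empty trajectory")
  if (stride < 1L) config_error("stride must be >= 1")
  if (stride >= n_frames) {
    data_error("stride (", stride, ") must be smaller than the frame count (", n_frames, ")")
  }
  cand <- hbond_candidates(trajectory$topology)
  frames <- seq.int(1L, n_frames, by = stride)
  X <- trajectory$xyz
  dmax2 <- criteria$d_max_A^2
  cDx <- 3L * cand$D - 2L; cAx <- 3L * cand$A - 2L; cHx <- 3L * cand$H - 2L
  ev_frames <- integer(0); ev_cand <- integer(0)
  ev_dist <- numeric(0); ev_ang <- numeric(0)
  if (nrow(cand)) {
    for (blk in split(frames, ceiling(seq_along(frames) / chunk_frames))) {
      sub <- X[blk, , drop = FALSE]
      d2 <- (sub[, cDx, drop = FALSE] - sub[, cAx, drop = FALSE])^2 +
            (sub[, cDx + 1L, drop = FALSE] - sub[, cAx + 1L, drop = FALSE])^2 +
            (sub[, cDx + 2L, drop = FALSE] - sub[, cAx + 2L, drop = FALSE])^2
      hit <- which(d2 <= dmax2, arr.ind = TRUE)
      if (!nrow(hit)) next
      fi <- hit[, 1L]; cj <- hit[, 2L]
      v1 <- cbind(sub[cbind(fi, cDx[cj])] - sub[cbind(fi, cHx[cj])],
                  sub[cbind(fi, cDx[cj] + 1L)] - sub[cbind(fi, cHx[cj] + 1L)],
                  sub[cbind(fi, cDx[cj] + 2L)] - sub[cbind(fi, cHx[cj] + 2L)])
      v2 <- cbind(sub[cbind(fi, cAx[cj])] - sub[cbind(fi, cHx[cj])],
                  sub[cbind(fi, cAx[cj] + 1L)] - sub[cbind(fi, cHx[cj] + 1L)],
                  sub[cbind(fi, cAx[cj] + 2L)] - sub[cbind(fi, cHx[cj] + 2L)])
      cosang <- rowSums(v1 * v2) / (sqrt(rowSums(v1 * v1)) * sqrt(rowSums(v2 * v2)))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      ok <- ang >= criteria$theta_min_deg
      ev_frames <- c(ev_frames, blk[fi[ok]])
      ev_cand <- c(ev_cand, cj[ok])
      ev_dist <- c(ev_dist, sqrt(d2[hit][ok]))
      ev_ang <- c(ev_ang, ang[ok])
    }
  }
  ord <- order(ev_frames, ev_cand)
  events <- hbond_event_frame(cand, ev_cand[ord], ev_dist[ord], ev_ang[ord])
  events <- cbind(frame = ev_frames[ord],
                  time_ns = (ev_frames[ord] - 1L) * trajectory$dt_ns, events)
  if (nrow(events)) {
    grp <- paste(events$protein_resid, events$species, sep = "|")
    n_bonds <- tapply(grp, grp, length)
    frames_present <- tapply(events$frame, grp, function(f) length(unique(f)))
    key <- names(n_bonds)
    parts <- do.call(rbind, strsplit(key, "|", fixed = TRUE))
    counts <- data.frame(
      protein_resid = parts[, 1], species = parts[, 2],
      n_bonds = as.integer(n_bonds), frames_present = as.integer(frames_present),
      stringsAsFactors = FALSE)
    counts$protein_resno <- events$protein_resno[match(counts$protein_resid, events$protein_resid)]
    counts <- counts[order(counts$protein_resno, counts$species), ]
    rownames(counts) <- NULL
  } else {
    counts <- data.frame(protein_resid = character(0), species = character(0),
                         n_bonds = integer(0), frames_present = integer(0),
                         protein_resno = integer(0))
  }
  structure(
    list(counts = counts, events = events, frame_indices = frames,
         n_frames_scanned = length(frames), total_frames = n_frames,
         stride = as.integer(stride), dt_ns = trajectory$dt_ns, criteria = criteria),
    class = "ContactTable")
}

#' @export
print.ContactTable <- function(x, ...) {
  cat("ContactTable:", nrow(x$events), "bond-frames over", x$n_frames_scanned,
      "frames (stride", x$stride, "),", nrow(x$counts), "(residue, species) pairs\n",
      "criteria: d_max =", x$criteria$d_max_A, "A, theta_min =",
      x$criteria$theta_min_deg, "deg\n")
  invisible(x)
}

#' Export a contact table and its events to CSV
#' @param contacts A `ContactTable`.
#' @param counts_path,events_path Output CSV paths (`NULL` to skip either).
#' @export
write_contact_table <- function(contacts, counts_path = NULL, events_path = NULL) {
  if (!is.null(counts_path)) {
    utils::write.csv(contacts$counts, counts_path, row.names = FALSE)
  }
  if (!is.null(events_path)) {
    utils::write.csv(contacts$events, events_path, row.names = FALSE)
  }
  invisible(contacts)
}
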