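# Ligand z-tracks relative to the membrane centre, pore-occupancy and
# extramembranous-contact residency events with gap merging, the
# duration filter (events longer than 4 ns are kept, per the strict
# inclusion rule), and pore transit summaries.

#' Ligand centre-of-geometry tracks along the membrane normal
#'
#' One track per ligand copy: per frame, the z of the ligand's heavy-atom
#' centre of geometry relative to the membrane centre, and the lateral
#' distance to the pore axis.
#'
#' @param trajectory A `Trajectory` with tagged ligands.
#' @param membrane A `MembraneFrame`.
#' @param species Species to include (default both).
#' @return Long data frame of class `LigandTracks`: `ligand`, `resno`,
#'   `species`, `frame`, `time_ns`, `z_A`, `lateral_A`, ordered by ligand
#'   then frame.
#' @export
ligand_tracks <- function(trajectory, membrane, species = c("alpha", "beta")) {
  topo <- trajectory$topology
  lig <- topo$residues[topo$residues$species %in% species, , drop = FALSE]
  n_frames <- nrow(trajectory$xyz)
  if (nrow(lig) == 0L) {
    warning("no ligands of requested species (", paste(species, collapse = ", "),
            ") are tagged", call. = FALSE)
    out <- data.frame(ligand = character(0), resno = integer(0),
                      species = character(0), frame = integer(0),
                      time_ns = numeric(0), z_A = numeric(0), lateral_A = numeric(0))
    class(out) <- c("LigandTracks", "data.frame")
    attr(out, "dt_ns") <- trajectory$dt_ns
    return(out)
  }
  lig <- lig[order(lig$resno, lig$resid), , drop = FALSE]
  pieces <- lapply(seq_len(nrow(lig)), function(k) {
    heavy <- which(topo$atoms$resid == lig$resid[k] & !topo$atoms$is_hydrogen)
    x <- rowMeans(trajectory$xyz[, 3L * heavy - 2L, drop = FALSE])
    y <- rowMeans(trajectory$xyz[, 3L * heavy - 1L, drop = FALSE])
    z <- rowMeans(trajectory$xyz[, 3L * heavy, drop = FALSE])
    data.frame(ligand = lig$resid[k], resno = lig$resno[k], species = lig$species[k],
               frame = seq_len(n_frames), time_ns = trajectory$times_ns,
               z_A = z - membrane$z_center_A,
               lateral_A = sqrt((x - membrane$pore_axis_xy[1])^2 +
                                (y - membrane$pore_axis_xy[2])^2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("LigandTracks", "data.frame")
  attr(out, "dt_ns") <- trajectory$dt_ns
  attr(out, "membrane") <- membrane
  out
}

# Maximal TRUE runs of a logical vector as (start, end) frame indices,
# merging runs separated by <= gap_frames FALSE frames.
runs_with_merge <- function(state, gap_frames) {
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (!length(on)) return(matrix(integer(0), ncol = 2))
  seg <- cbind(starts[on], ends[on])
  merged <- seg[1, , drop = FALSE]
  for (k in seq_len(nrow(seg) - 1L) + 1L) {
    gap <- seg[k, 1] - merged[nrow(merged), 2] - 1L
    if (gap <= gap_frames) {
      merged[nrow(merged), 2] <- seg[k, 2]
    } else {
      merged <- rbind(merged, seg[k, ])
    }
  }
  merged
}

#' Detect ligand residency events
#'
#' Pore events are maximal runs of frames with `|z| <= half_thickness` and
#' `lateral <= pore_radius`; extramembranous-contact events are maximal
#' runs of frames in which the ligand holds at least one hydrogen bond to
#' a residue in the extracellular or intracellular region. Runs separated
#' by gaps of at most `gap_tolerance_ns` are merged (flicker suppression);
#' `gap_tolerance_ns = 0` disables merging. Event duration is
#' `span_frames * dt` (closed on both endpoint frames).
#'
#' @param tracks A `LigandTracks` object.
#' @param membrane A `MembraneFrame`.
#' @param contacts Optional `ContactTable` (stride 1, same trajectory) for
#'   extramembranous-contact events.
#' @param regions Named region vector from [residue_regions()]; required
#'   with `contacts`.
#' @param gap_tolerance_ns Maximum gap to bridge when merging (default 0.5).
#' @return Data frame of events: `ligand`, `species`, `location`
#'   (`pore` / `extramembranous_contact`), `start_frame`, `end_frame`,
#'   `n_frames_span`, `n_frames_in_state`, `start_ns`, `end_ns`,
#'   `duration_ns`.
#' @export
detect_residency_events <- function(tracks, membrane, contacts = NULL,
                                    regions = NULL, gap_tolerance_ns = 0.5) {
  dt <- attr(tracks, "dt_ns")
  gap_frames <- floor(gap_tolerance_ns / dt + 1e-9)
  ligs <- unique(tracks[, c("ligand", "resno", "species")])
  n_frames <- max(tracks$frame, 0L)
  contact_frames <- NULL
  if (!is.null(contacts)) {
    if (is.null(regions)) config_error("regions are required with contacts")
    if (!identical(as.integer(contacts$frame_indices), seq_len(n_frames))) {
      data_error("shape mismatch: contact table frames do not match tracks ",
                 "(stride-1 contacts on the same trajectory are required)")
    }
    ev <- contacts$events
    extramem <- names(regions)[regions %in% c("extracellular", "intracellular")]
    ev <- ev[ev$protein_resid %in% extramem, , drop = FALSE]
    contact_frames <- split(ev$frame, ev$ligand_resid)
  }
  out <- list()
  for (k in seq_len(nrow(ligs))) {
    tr <- tracks[tracks$ligand == ligs$ligand[k], , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    in_pore <- abs(tr$z_A) <= membrane$half_thickness_A &
      tr$lateral_A <= membrane$pore_radius_A
    states <- list(pore = in_pore)
    if (!is.null(contact_frames)) {
      cf <- contact_frames[[ligs$ligand[k]]]
      in_contact <- rep(FALSE, nrow(tr))
      if (!is.null(cf)) in_contact[unique(cf)] <- TRUE
      states$extramembranous_contact <- in_contact
    }
    for (loc in names(states)) {
      seg <- runs_with_merge(states[[loc]], gap_frames)
      if (!nrow(seg)) next
      in_state <- vapply(seq_len(nrow(seg)),
                         function(s) sum(states[[loc]][seg[s, 1]:seg[s, 2]]), 0L)
      span <- seg[, 2] - seg[, 1] + 1L
      out[[length(out) + 1L]] <- data.frame(
        ligand = ligs$ligand[k], resno = ligs$resno[k], species = ligs$species[k],
        location = loc, start_frame = seg[, 1], end_frame = seg[, 2],
        n_frames_span = span, n_frames_in_state = in_state,
        start_ns = (seg[, 1] - 1L) * dt, end_ns = (seg[, 1] - 1L) * dt + span * dt,
        duration_ns = span * dt, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    res <- data.frame(ligand = character(0), resno = integer(0), species = character(0),
                      location = character(0), start_frame = integer(0),
                      end_frame = integer(0), n_frames_span = integer(0),
                      n_frames_in_state = integer(0), start_ns = numeric(0),
                      end_ns = numeric(0), duration_ns = numeric(0))
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$resno, res$location, res$start_frame), ]
    rownames(res) <- NULL
  }
  attr(res, "dt_ns") <- dt
  attr(res, "gap_tolerance_ns") <- gap_tolerance_ns
  res
}

#' Filter residency events by duration
#'
#' Keeps events longer than `min_duration_ns` (strictly, by default, per
#' the "longer than 4 ns" inclusion rule; `strict = FALSE` also keeps
#' events exactly at the threshold). The attached exclusion report gives
#' the excluded fraction and the fraction of excluded events shorter than
#' 2 ns.
#'
#' @param events Event data frame from [detect_residency_events()].
#' @param min_duration_ns Duration threshold in ns (default 4).
#' @param strict Use `>` (default) rather than `>=`.
#' @return Surviving events, with a `cumulative_ns` column (total residence
#'   per ligand/location across all unfiltered events) and attribute
#'   `exclusion_report`.
#' @export
filter_events <- function(events, min_duration_ns = 4.0, strict = TRUE) {
  keep <- if (strict) events$duration_ns > min_duration_ns else
    events$duration_ns >= min_duration_ns
  n_total <- nrow(events)
  n_excl <- sum(!keep)
  report <- list(
    n_total = n_total, n_excluded = n_excl,
    excluded_fraction = if (n_total) n_excl / n_total else NA_real_,
    excluded_lt2ns_fraction = if (n_excl) mean(events$duration_ns[!keep] < 2) else NA_real_,
    min_duration_ns = min_duration_ns, strict = strict,
    note = if (!n_total) "no events to filter" else NULL)
  out <- events[keep, , drop = FALSE]
  if (n_total) {
    cum <- tapply(events$duration_ns, paste(events$ligand, events$location), sum)
    out$cumulative_ns <- as.numeric(cum[paste(out$ligand, out$location)])
  } else {
    out$cumulative_ns <- numeric(0)
  }
  rownames(out) <- NULL
  attr(out, "exclusion_report") <- report
  attr(out, "dt_ns") <- attr(events, "dt_ns")
  out
}

#' Pore entry, exit and permeation counts per species
#'
#' For each pore event, the side of approach is the sign of the relative z
#' at the nearest out-of-pore frame before the event (positive =
#' extracellular), and the side of departure the sign just after. An entry
#' is a pore event approached from the extracellular side; an exit is one
#' leaving to the intracellular side; a full permeation is one whose
#' flanking signs differ. Events touching the trajectory ends lack a
#' flanking frame on that side and do not count there.
#'
#' @param events Events from [detect_residency_events()] (pore rows used).
#' @param tracks The matching `LigandTracks`.
#' @return Data frame per species: `n_entries`, `n_exits`, `n_permeations`.
#' @export
pore_transit_summary <- function(events, tracks) {
  ev <- events[events$location == "pore", , drop = FALSE]
  n_frames <- max(tracks$frame, 0L)
  res <- data.frame(species = c("alpha", "beta"), n_entries = 0L,
                    n_exits = 0L, n_permeations = 0L, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(ev))) {
    tr <- tracks[tracks$ligand == ev$ligand[k], , drop = FALSE]
    z_before <- if (ev$start_frame[k] > 1L) tr$z_A[tr$frame == ev$start_frame[k] - 1L] else NA_real_
    z_after <- if (ev$end_frame[k] < n_frames) tr$z_A[tr$frame == ev$end_frame[k] + 1L] else NA_real_
    i <- match(ev$species[k], res$species)
    if (!is.na(z_before) && z_before > 0) res$n_entries[i] <- res$n_entries[i] + 1L
    if (!is.na(z_after) && z_after < 0) res$n_exits[i] <- res$n_exits[i] + 1L
    if (!is.na(z_before) && !is.na(z_after) && sign(z_before) != sign(z_after)) {
      res$n_permeations[i] <- res$n_permeations[i] + 1L
    }
  }
  res
}
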