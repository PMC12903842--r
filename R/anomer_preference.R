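# Per-residue alpha/beta hydrogen-bond preference ratios, threshold
# classification, membrane-region assignment and summaries, and
# mixed-vs-single-anomer proportion shifts.

#' Preference-classification thresholds
#'
#' A residue's preference ratio is its alpha bond count divided by its beta
#' bond count. Ratios at or above `alpha_min_ratio` classify as
#' alpha-preferring, at or below `beta_max_ratio` as beta-preferring
#' (both boundaries inclusive); residues with fewer than `min_total_bonds`
#' total bonds are reported as `insufficient` rather than classified.
#'
#' @param alpha_min_ratio Lower ratio bound for alpha preference (default 1.4).
#' @param beta_max_ratio Upper ratio bound for beta preference (default 0.7).
#' @param min_total_bonds Minimum alpha + beta bonds before classifying
#'   (default 10).
#' @export
preference_thresholds <- function(alpha_min_ratio = 1.4, beta_max_ratio = 0.7,
                                  min_total_bonds = 10L) {
  if (!(beta_max_ratio < alpha_min_ratio)) {
    config_error("beta_max_ratio must be < alpha_min_ratio")
  }
  if (min_total_bonds < 1L) config_error("min_total_bonds must be >= 1")
  structure(list(alpha_min_ratio = alpha_min_ratio, beta_max_ratio = beta_max_ratio,
                 min_total_bonds = as.integer(min_total_bonds)),
            class = "PreferenceThresholds")
}

#' Anomer preference ratio and classification
#'
#' Vectorised over count pairs. The ratio is `N_alpha / N_beta`, `Inf` when
#' `N_beta` is zero (an all-alpha residue is maximally alpha-preferring).
#'
#' @param n_alpha,n_beta Non-negative bond counts.
#' @param thresholds A [preference_thresholds()] object.
#' @return Data frame with columns `ratio` and `classification`
#'   (`alpha`/`beta`/`none`/`insufficient`).
#' @export
preference_ratio <- function(n_alpha, n_beta, thresholds = preference_thresholds()) {
  stopifnot(all(n_alpha >= 0), all(n_beta >= 0))
  ratio <- ifelse(n_beta > 0, n_alpha / n_beta, Inf)
  cls <- ifelse(n_alpha + n_beta < thresholds$min_total_bonds, "insufficient",
         ifelse(ratio >= thresholds$alpha_min_ratio, "alpha",
         ifelse(ratio <= thresholds$beta_max_ratio, "beta", "none")))
  data.frame(ratio = ratio, classification = cls, stringsAsFactors = FALSE)
}

#' Assign membrane regions from relative z and lateral pore distance
#'
#' Extracellular above the slab (`z > +half_thickness`), intracellular
#' below it, pore inside the slab within the pore radius, `other`
#' otherwise. Vectorised.
#'
#' @param z_rel_A z relative to the membrane centre (Angstrom).
#' @param lateral_A Lateral distance to the pore axis (Angstrom).
#' @param membrane A `MembraneFrame`.
#' @export
assign_region <- function(z_rel_A, lateral_A, membrane) {
  h <- membrane$half_thickness_A
  ifelse(z_rel_A > h, "extracellular",
  ifelse(z_rel_A < -h, "intracellular",
  ifelse(lateral_A <= membrane$pore_radius_A, "pore", "other")))
}

#' Region of each protein residue
#'
#' Computes the region of every protein residue from its CA position in the
#' first frame (region identity is treated as static).
#'
#' @param trajectory A `Trajectory` (first frame is used).
#' @param membrane A `MembraneFrame`.
#' @return Named character vector of regions, names are residue keys.
#' @export
residue_regions <- function(trajectory, membrane) {
  topo <- trajectory$topology
  prot <- topo$residues$resid[topo$residues$species == "protein"]
  ca <- which(topo$atoms$elety == "CA" & topo$atoms$resid %in% prot)
  xyz1 <- trajectory$xyz[1L, ]
  x <- xyz1[3L * ca - 2L]; y <- xyz1[3L * ca - 1L]; z <- xyz1[3L * ca]
  z_rel <- z - membrane$z_center_A
  lateral <- sqrt((x - membrane$pore_axis_xy[1])^2 + (y - membrane$pore_axis_xy[2])^2)
  stats::setNames(assign_region(z_rel, lateral, membrane), topo$atoms$resid[ca])
}

#' Per-residue preference table from a mixed-anomer contact table
#'
#' One record per protein residue with nonzero contacts, ordered by residue
#' number: alpha and beta counts, ratio, threshold classification, and
#' membrane region.
#'
#' @param contacts A `ContactTable` from a mixed-species trajectory.
#' @param regions Named region vector from [residue_regions()] (optional;
#'   unmatched residues get region `other`).
#' @param thresholds A [preference_thresholds()] object.
#' @param count `"bonds"` (bond-frame counts, default) or `"frames"`
#'   (presence counts).
#' @return Data frame of class `PreferenceTable`.
#' @export
build_preference_table <- function(contacts, regions = NULL,
                                   thresholds = preference_thresholds(),
                                   count = c("bonds", "frames")) {
  count <- match.arg(count)
  cts <- contacts$counts
  value <- if (count == "bonds") cts$n_bonds else cts$frames_present
  resids <- unique(cts$protein_resid)
  n_alpha <- n_beta <- stats::setNames(integer(length(resids)), resids)
  ia <- cts$species == "alpha"; ib <- cts$species == "beta"
  n_alpha[cts$protein_resid[ia]] <- value[ia]
  n_beta[cts$protein_resid[ib]] <- value[ib]
  if (length(resids) && (all(n_alpha == 0L) || all(n_beta == 0L))) {
    warning("one species has no contacts at all; ratios are degenerate ",
            "(is this a single-anomer trajectory?)", call. = FALSE)
  }
  pr <- preference_ratio(n_alpha, n_beta, thresholds)
  region <- if (is.null(regions)) rep("other", length(resids)) else {
    r <- unname(regions[resids]); r[is.na(r)] <- "other"; r
  }
  out <- data.frame(
    residue = resids,
    resno = cts$protein_resno[match(resids, cts$protein_resid)],
    n_alpha = unname(n_alpha), n_beta = unname(n_beta),
    ratio = pr$ratio, classification = pr$classification, region = region,
    stringsAsFactors = FALSE)
  out <- out[order(out$resno, out$residue), ]
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  attr(out, "count") <- count
  class(out) <- c("PreferenceTable", "data.frame")
  out
}

#' Per-region tallies of preference classes
#'
#' Counts alpha-, beta- and none-classified residues per membrane region;
#' `insufficient` residues are excluded from the tallies (and reported in
#' their own column).
#'
#' @param records A `PreferenceTable`.
#' @return Data frame with one row per region.
#' @export
region_summary <- function(records) {
  regions <- c("extracellular", "pore", "intracellular", "other")
  tab <- table(factor(records$region, levels = regions),
               factor(records$classification,
                      levels = c("alpha", "beta", "none", "insufficient")))
  data.frame(region = regions,
             n_alpha_pref = as.integer(tab[, "alpha"]),
             n_beta_pref = as.integer(tab[, "beta"]),
             n_none = as.integer(tab[, "none"]),
             n_insufficient = as.integer(tab[, "insufficient"]),
             stringsAsFactors = FALSE)
}

#' Mixed-vs-single-anomer bond-share shifts
#'
#' For one species, each residue's share is its bond count divided by the
#' species total within that condition; the shift is the mixed-condition
#' share minus the single-condition share. Residues whose absolute shift
#' reaches `min_share_delta` are flagged as candidates for cooperative
#' (anomer-interaction) effects.
#'
#' @param table_mixed,table_single `ContactTable`s from a mixed- and a
#'   single-anomer run covering the same system.
#' @param species `"alpha"` or `"beta"`.
#' @param min_share_delta Absolute share change that triggers the flag
#'   (default 0.02).
#' @param count `"bonds"` or `"frames"` counting mode.
#' @return Data frame with shares, `delta`, and `flagged_cooperative`.
#' @export
proportion_shift <- function(table_mixed, table_single, species,
                             min_share_delta = 0.02, count = c("bonds", "frames")) {
  count <- match.arg(count)
  species <- match.arg(species, c("alpha", "beta"))
  pick <- function(tab) {
    cts <- tab$counts[tab$counts$species == species, , drop = FALSE]
    stats::setNames(if (count == "bonds") cts$n_bonds else cts$frames_present,
                    cts$protein_resid)
  }
  nm <- pick(table_mixed); ns <- pick(table_single)
  if (sum(nm) == 0L || sum(ns) == 0L) {
    data_error("species '", species, "' absent from one condition; ",
               "shares are undefined (degenerate condition)")
  }
  resids <- sort(union(names(nm), names(ns)))
  getn <- function(v) { x <- v[resids]; x[is.na(x)] <- 0L; unname(x) }
  share_mixed <- getn(nm) / sum(nm)
  share_single <- getn(ns) / sum(ns)
  delta <- share_mixed - share_single
  resno_lookup <- rbind(table_mixed$counts, table_single$counts)
  out <- data.frame(
    residue = resids,
    resno = resno_lookup$protein_resno[match(resids, resno_lookup$protein_resid)],
    species = species,
    share_single = share_single, share_mixed = share_mixed, delta = delta,
    flagged_cooperative = abs(delta) >= min_share_delta,
    stringsAsFactors = FALSE)
  out <- out[order(out$resno, out$residue), ]
  rownames(out) <- NULL
  out
}
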