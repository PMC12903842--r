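# Least-squares rigid superposition, windowed per-residue CA RMSF,
# between-condition difference maps (first argument minus second; positive
# cells mean the first condition fluctuates more), and pairwise
# minimum-distance time series for salt-bridge monitoring.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `frame` onto `reference` over a selection, and applies it to the whole
#' frame.
#'
#' @param frame,reference n x 3 coordinate matrices (or flat vectors).
#' @param selection Atom indices used for the fit (default: all atoms).
#' @return A `Superposition`: `rotation` (3 x 3, det +1), `translation`
#'   (length 3; transformed = coords %*% t(rotation) + translation),
#'   `rmsd_A` over the selection, and the transformed `coords`.
#' @export
superpose <- function(frame, reference, selection = NULL) {
  P <- as_coord_matrix(frame)
  Q <- as_coord_matrix(reference)
  if (is.null(selection)) selection <- seq_len(nrow(P))
  if (length(selection) < 3L) data_error("superposition needs >= 3 selected atoms")
  Ps <- P[selection, , drop = FALSE]
  Qs <- Q[selection, , drop = FALSE]
  cp <- colMeans(Ps); cq <- colMeans(Qs)
  Pc <- sweep(Ps, 2, cp); Qc <- sweep(Qs, 2, cq)
  if (svd(Pc)$d[2] < 1e-8) data_error("degenerate fit: selection is (near-)collinear")
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  translation <- cq - as.numeric(cp %*% t(R))
  transformed <- P %*% t(R) + rep(translation, each = nrow(P))
  rmsd <- sqrt(mean(rowSums((transformed[selection, , drop = FALSE] - Qs)^2)))
  structure(list(rotation = R, translation = translation, rmsd_A = rmsd,
                 coords = transformed),
            class = "Superposition")
}

# Frames whose time falls in [k*len, (k+1)*len). The trajectory span is
# n_frames * dt (each frame stands for one sampling interval), so a 250 ns
# trajectory at dt = 0.1 has 2500 frames and tiles into exactly ten 25 ns
# windows.
window_frame_index <- function(trajectory, start_ns, end_ns) {
  t <- trajectory$times_ns
  which(t >= start_ns - 1e-9 & t < end_ns - 1e-9)
}

#' Per-atom RMSF over a time window
#'
#' RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2), the fluctuation about the
#' within-window mean position. With `fit = TRUE` every window frame is
#' first superposed onto the window's first frame over the selection, so
#' rigid-body motion does not inflate fluctuations.
#'
#' @param trajectory A `Trajectory`.
#' @param selection Atom indices (typically CA) to report.
#' @param window_ns `c(start, end)` in ns, or `NULL` for the full span.
#' @param fit Superpose frames before measuring (default `TRUE`).
#' @return An `RMSFProfile`: per-selected-atom RMSF (Angstrom) named by
#'   residue key, plus window and fit metadata.
#' @export
rmsf <- function(trajectory, selection, window_ns = NULL, fit = TRUE) {
  if (length(selection) == 0L) data_error("empty selection")
  if (is.null(window_ns)) window_ns <- c(0, nrow(trajectory$xyz) * trajectory$dt_ns)
  frames <- window_frame_index(trajectory, window_ns[1], window_ns[2])
  if (length(frames) < 2L) {
    data_error("window [", window_ns[1], ", ", window_ns[2], ") ns holds ",
               length(frames), " frame(s); >= 2 required")
  }
  cols <- as.vector(rbind(3L * selection - 2L, 3L * selection - 1L, 3L * selection))
  if (fit) {
    ref <- frame_coords(trajectory, frames[1L])
    sub <- matrix(0, length(frames), length(cols))
    for (k in seq_along(frames)) {
      fitted <- superpose(frame_coords(trajectory, frames[k]), ref, selection)$coords
      sub[k, ] <- as.vector(t(fitted[selection, , drop = FALSE]))
    }
  } else {
    sub <- trajectory$xyz[frames, cols, drop = FALSE]
  }
  # population variance per coordinate, summed over x,y,z per atom
  var_col <- colMeans(sub^2) - colMeans(sub)^2
  msf <- colSums(matrix(var_col, nrow = 3L))
  vals <- sqrt(pmax(msf, 0))
  names(vals) <- trajectory$topology$atoms$resid[selection]
  structure(list(window_ns = window_ns, rmsf_A = vals, selection = selection,
                 resno = trajectory$topology$atoms$resno[selection], fit = fit),
            class = "RMSFProfile")
}

#' Sliding-window RMSF matrix
#'
#' Partitions the trajectory into contiguous non-overlapping windows of
#' `window_len_ns` starting at t = 0 (window count =
#' floor(span / length); a trailing remainder is dropped with a message)
#' and computes [rmsf()] in each.
#'
#' @param trajectory A `Trajectory`.
#' @param selection Atom indices (typically CA).
#' @param window_len_ns Window length in ns (<= trajectory span).
#' @param fit Superpose within each window onto its first frame.
#' @param condition Label for the condition (e.g. `"alpha"`, `"mixed"`).
#' @return An `RMSFMatrix`: `values` (selected atoms x windows, Angstrom),
#'   window midpoints, length, and the condition label.
#' @export
sliding_window_rmsf <- function(trajectory, selection, window_len_ns,
                                fit = TRUE, condition = "") {
  span <- nrow(trajectory$xyz) * trajectory$dt_ns
  n_win <- floor(span / window_len_ns + 1e-9)
  if (n_win < 1L) {
    data_error("window length ", window_len_ns, " ns exceeds trajectory span ",
               span, " ns")
  }
  remainder <- span - n_win * window_len_ns
  if (remainder > 1e-9) {
    message("dropping trailing ", signif(remainder, 4), " ns (",
            round(remainder / trajectory$dt_ns), " frames) beyond window ", n_win)
  }
  vals <- vapply(seq_len(n_win), function(k) {
    rmsf(trajectory, selection,
         window_ns = c((k - 1) * window_len_ns, k * window_len_ns), fit = fit)$rmsf_A
  }, numeric(length(selection)))
  vals <- matrix(vals, nrow = length(selection),
                 dimnames = list(trajectory$topology$atoms$resid[selection], NULL))
  structure(list(values = vals, window_len_ns = window_len_ns,
                 window_mid_ns = (seq_len(n_win) - 0.5) * window_len_ns,
                 resno = trajectory$topology$atoms$resno[selection],
                 condition = condition, fit = fit),
            class = "RMSFMatrix")
}

#' Between-condition RMSF difference map
#'
#' Elementwise `A - B` on two RMSF matrices over the same residues and
#' window grid. Positive cells mean condition A fluctuates more (rendered
#' red in the conventional heatmap; e.g. RMSF_alpha - RMSF_beta > 0).
#'
#' @param A,B `RMSFMatrix` objects with identical shape and residues.
#' @return An `RMSFDiffMap`.
#' @export
rmsf_difference <- function(A, B) {
  if (!identical(dim(A$values), dim(B$values)) ||
      !identical(rownames(A$values), rownames(B$values))) {
    data_error("shape mismatch: RMSF matrices differ in residues or windows")
  }
  structure(list(values = A$values - B$values, window_len_ns = A$window_len_ns,
                 window_mid_ns = A$window_mid_ns, resno = A$resno,
                 labels = c(A = A$condition, B = B$condition)),
            class = "RMSFDiffMap")
}

#' Minimum-distance time series between two atom selections
#'
#' Per frame, the minimum over all cross pairs -- the standard salt-bridge
#' monitor (e.g. Arg guanidinium vs Glu carboxylate atoms). A distance
#' below ~4 Angstrom is conventionally annotated as a formed salt bridge.
#'
#' @param trajectory A `Trajectory`.
#' @param sel_a,sel_b Non-empty atom index vectors.
#' @return Data frame `frame`, `time_ns`, `distance_A`.
#' @export
pair_distance_timeseries <- function(trajectory, sel_a, sel_b) {
  if (!length(sel_a) || !length(sel_b)) data_error("empty selection")
  X <- trajectory$xyz
  dmin <- rep(Inf, nrow(X))
  for (i in sel_a) {
    for (j in sel_b) {
      d <- sqrt((X[, 3 * i - 2] - X[, 3 * j - 2])^2 +
                (X[, 3 * i - 1] - X[, 3 * j - 1])^2 +
                (X[, 3 * i] - X[, 3 * j])^2)
      dmin <- pmin(dmin, d)
    }
  }
  data.frame(frame = seq_len(nrow(X)), time_ns = trajectory$times_ns,
             distance_A = dmin)
}

#' Export an RMSF matrix (or difference map) to CSV
#'
#' Rows are residues, columns are window midpoints in ns.
#' @param m An `RMSFMatrix` or `RMSFDiffMap`.
#' @param path Output CSV path.
#' @export
write_rmsf_matrix <- function(m, path) {
  df <- data.frame(residue = rownames(m$values), resno = m$resno,
                   m$values, check.names = FALSE)
  colnames(df)[-(1:2)] <- sprintf("t%.1f", m$window_mid_ns)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(m)
}
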