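# Plain-text / binary format emitters for the synthetic generator, plus the
# PSF bond-list parser. bio3d reads PDB and DCD; it offers no multi-model
# PDB writer, DCD writer, or PSF reader, so those live here.

pdb_atom_line <- function(eleno, name, resname, chain, resno, x, y, z, element) {
  # Strict PDB v3 columns; 1-3 character atom names start in column 14.
  sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          eleno %% 100000L, name, resname, chain, resno %% 10000L, x, y, z, element)
}

pdb_model_lines <- function(atoms, coords) {
  pdb_atom_line(atoms$eleno, atoms$elety, atoms$resname, atoms$chain,
                atoms$resno, coords[, 1], coords[, 2], coords[, 3], atoms$element)
}

#' Write a topology as a single-model PDB file
#' @param topology A `Topology`; reference coordinates are written.
#' @param path Output file path.
#' @export
write_topology_pdb <- function(topology, path) {
  coords <- matrix(topology$xyz0, ncol = 3, byrow = TRUE)
  writeLines(c(pdb_model_lines(topology$atoms, coords), "END"), path)
  invisible(path)
}

write_trajectory_pdb <- function(trajectory, path) {
  atoms <- trajectory$topology$atoms
  n <- nrow(trajectory$xyz)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    coords <- matrix(trajectory$xyz[i, ], ncol = 3, byrow = TRUE)
    writeLines(c(sprintf("MODEL     %4d", i),
                 pdb_model_lines(atoms, coords), "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

# CHARMM-style DCD: Fortran sequential records, little-endian, single
# precision coordinates, no unit-cell block (icntrl[11] = 0, version 24).
write_trajectory_dcd <- function(trajectory, path) {
  xyz <- trajectory$xyz
  natoms <- as.integer(ncol(xyz) / 3)
  nframes <- nrow(xyz)
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    tc <- rawConnection(raw(0), "wb")
    writer(tc)
    bytes <- rawConnectionValue(tc)
    close(tc)
    writeBin(length(bytes), con, size = 4L, endian = "little")
    writeBin(bytes, con)
    writeBin(length(bytes), con, size = 4L, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nframes; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nframes
  icntrl[20] <- 24L
  rec(function(c2) {
    writeChar("CORD", c2, 4L, eos = NULL)
    writeBin(icntrl, c2, size = 4L, endian = "little")
  })
  rec(function(c2) {
    writeBin(1L, c2, size = 4L, endian = "little")
    writeChar(sprintf("%-80s", "anomertraj synthetic trajectory"), c2, 80L, eos = NULL)
  })
  rec(function(c2) writeBin(natoms, c2, size = 4L, endian = "little"))
  xcol <- 3L * seq_len(natoms) - 2L
  for (i in seq_len(nframes)) {
    for (k in 0:2) {
      v <- xyz[i, xcol + k]
      rec(function(c2) writeBin(v, c2, size = 4L, endian = "little"))
    }
  }
  invisible(path)
}

#' Write a minimal PSF connectivity file
#'
#' Emits the `!NATOM` and `!NBOND` sections (X-PLOR-style layout) for a
#' topology whose bond list is populated, sufficient for connectivity-aware
#' donor/acceptor derivation on re-read.
#' @param topology A `Topology` with a bond list.
#' @param path Output file path.
#' @export
write_topology_psf <- function(topology, path) {
  if (is.null(topology$bonds)) config_error("topology has no bond list to write")
  atoms <- topology$atoms
  n <- nrow(atoms)
  lines <- c("PSF", "", sprintf("%8d !NTITLE", 1L),
             " REMARKS anomertraj synthetic topology", "",
             sprintf("%8d !NATOM", n),
             sprintf("%8d %-4s %-4d %-4s %-4s %-4s %10.6f %13.4f %11d",
                     seq_len(n), atoms$chain, atoms$resno, atoms$resname,
                     atoms$elety, atoms$elety, 0, 1, 0),
             "")
  pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- topology$bonds[[i]]
    nb <- nb[nb > i]
    if (length(nb)) cbind(i, nb)
  }))
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2)
  lines <- c(lines, sprintf("%8d !NBOND: bonds", nrow(pairs)))
  flat <- as.integer(t(pairs))
  if (length(flat)) {
    grp <- split(flat, ceiling(seq_along(flat) / 8))
    lines <- c(lines, vapply(grp, function(g) paste(sprintf("%8d", g), collapse = ""), ""))
  }
  writeLines(c(lines, ""), path)
  invisible(path)
}

# Parse the !NBOND section of a PSF file into a per-atom neighbour list.
read_psf_bonds <- function(path, n_atoms) {
  if (!file.exists(path)) data_error("cannot read PSF file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("!NBOND", lines)
  if (length(hdr) != 1L) data_error("PSF file has no !NBOND section: ", path)
  nbond <- as.integer(sub("^\\s*(\\d+).*$", "\\1", lines[hdr]))
  ints <- integer(0)
  i <- hdr + 1L
  while (length(ints) < 2L * nbond && i <= length(lines)) {
    ints <- c(ints, as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1L
  }
  if (length(ints) < 2L * nbond) data_error("truncated !NBOND section in ", path)
  pairs <- matrix(ints[seq_len(2L * nbond)], ncol = 2, byrow = TRUE)
  if (any(pairs < 1L) || any(pairs > n_atoms)) {
    data_error("PSF bond indices outside 1..", n_atoms)
  }
  bonds <- vector("list", n_atoms)
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    bonds[[a]] <- c(bonds[[a]], b)
    bonds[[b]] <- c(bonds[[b]], a)
  }
  bonds
}

#' Write a trajectory to disk
#'
#' @param trajectory A `Trajectory`.
#' @param path Output path.
#' @param format `"pdb"` (multi-model, fixed 0.001 A precision) or `"dcd"`
#'   (binary, single precision).
#' @export
emit_trajectory <- function(trajectory, path, format = c("pdb", "dcd")) {
  if (length(format) == 1L && !format %in% c("pdb", "dcd")) {
    config_error("unsupported trajectory format: ", format)
  }
  format <- match.arg(format)
  switch(format,
         pdb = write_trajectory_pdb(trajectory, path),
         dcd = write_trajectory_dcd(trajectory, path))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
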