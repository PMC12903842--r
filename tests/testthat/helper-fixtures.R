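# Fixtures are built in code at test time; no data files are shipped.

# Minimal three-atom PDB: a hydroxyl donor (O-H) and an acceptor nitrogen.
write_tiny_pdb <- function(path, h_x = 0.96) {
  lines <- c(
    anomertraj:::pdb_atom_line(1L, "OG", "SER", "A", 1L, 0, 0, 0, "O"),
    anomertraj:::pdb_atom_line(2L, "HG", "SER", "A", 1L, h_x, 0, 0, "H"),
    anomertraj:::pdb_atom_line(3L, "N", "GLY", "A", 2L, 3, 0, 0, "N"),
    "END")
  writeLines(lines, path)
  path
}

# A topology of n isolated CA atoms (one residue each) for RMSF tests.
make_ca_topology <- function(n) {
  atoms <- data.frame(
    eleno = seq_len(n), elety = "CA", element = "C",
    resno = seq_len(n), resname = "GLY", chain = "A",
    is_hydrogen = FALSE, stringsAsFactors = FALSE)
  anomertraj:::new_topology(atoms, rep(0, 3 * n))
}

# Random "soup" of protein and ligand residues with donors/acceptors and
# coordinates in a tight box, for oracle-equivalence testing.
random_soup_topology <- function(n_prot = 10, n_lig = 8, box = 10, seed = 1) {
  set.seed(seed)
  elety <- character(0); element <- character(0); resno <- integer(0)
  resname <- character(0); chain <- character(0); ish <- logical(0)
  coords <- matrix(numeric(0), ncol = 3)
  bonds_pairs <- matrix(integer(0), ncol = 2)
  add <- function(ty, el, rn, rnm, ch, pos) {
    elety <<- c(elety, ty); element <<- c(element, el)
    resno <<- c(resno, rn); resname <<- c(resname, rnm); chain <<- c(chain, ch)
    ish <<- c(ish, el == "H")
    coords <<- rbind(coords, pos)
    length(elety)
  }
  rnd <- function() stats::runif(3, -box / 2, box / 2)
  h_off <- function() {
    v <- stats::rnorm(3)
    0.96 * v / sqrt(sum(v^2))
  }
  for (r in seq_len(n_prot)) {
    base <- rnd()
    add("CA", "C", r, "ALA", "A", base)
    heavy <- add(sample(c("N", "O"), 1), sample(c("N", "O"), 1), r, "ALA", "A",
                 base + stats::rnorm(3, sd = 0.8))
    element[heavy] <- substr(elety[heavy], 1, 1)
    if (stats::runif(1) < 0.8) {
      h <- add("H", "H", r, "ALA", "A", coords[heavy, ] + h_off())
      bonds_pairs <- rbind(bonds_pairs, c(heavy, h))
    }
  }
  for (l in seq_len(n_lig)) {
    rn <- 100L + l
    nm <- if (l %% 2L) "GLC" else "BGC"
    o <- add("O1", "O", rn, nm, "L", rnd())
    h <- add("H1", "H", rn, nm, "L", coords[o, ] + h_off())
    bonds_pairs <- rbind(bonds_pairs, c(o, h))
  }
  n <- length(elety)
  bonds <- vector("list", n)
  for (k in seq_len(nrow(bonds_pairs))) {
    a <- bonds_pairs[k, 1]; b <- bonds_pairs[k, 2]
    bonds[[a]] <- c(bonds[[a]], b); bonds[[b]] <- c(bonds[[b]], a)
  }
  atoms <- data.frame(eleno = seq_len(n), elety = elety, element = element,
                      resno = resno, resname = resname, chain = chain,
                      is_hydrogen = ish, stringsAsFactors = FALSE)
  topo <- anomertraj:::new_topology(atoms, as.vector(t(coords)), bonds)
  suppressMessages(tag_ligand_species(topo, c(GLC = "alpha", BGC = "beta")))
}

# Canonical ordering of hydrogen-bond events for set comparison.
canon_events <- function(ev) {
  ev <- ev[order(ev$donor_atom, ev$hydrogen_atom, ev$acceptor_atom), ]
  rownames(ev) <- NULL
  ev
}

expect_same_events <- function(a, b, tol = 1e-9) {
  a <- canon_events(a); b <- canon_events(b)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$donor_atom, b$donor_atom)
  expect_equal(a$hydrogen_atom, b$hydrogen_atom)
  expect_equal(a$acceptor_atom, b$acceptor_atom)
  expect_equal(a$species, b$species)
  expect_equal(a$distance_A, b$distance_A, tolerance = tol)
  expect_equal(a$angle_deg, b$angle_deg, tolerance = tol)
}

# Hand-built LigandTracks object for residency tests.
make_tracks <- function(z, lateral = 0, dt = 0.1, species = "alpha",
                        ligand = "L:101", resno = 101L) {
  out <- data.frame(ligand = ligand, resno = resno, species = species,
                    frame = seq_along(z), time_ns = (seq_along(z) - 1) * dt,
                    z_A = z, lateral_A = rep_len(lateral, length(z)),
                    stringsAsFactors = FALSE)
  class(out) <- c("LigandTracks", "data.frame")
  attr(out, "dt_ns") <- dt
  out
}

toy_membrane <- function(half = 15, pore = 10) {
  structure(list(z_center_A = 0, half_thickness_A = half,
                 pore_axis_xy = c(0, 0), pore_radius_A = pore),
            class = "MembraneFrame")
}

# Small mixed-anomer synthetic system shared across tests.
toy_flooding <- function(n_frames = 1500, seed = 11,
                         propensities = data.frame(
                           resno = c(2, 5, 8, 20),
                           p_alpha = c(0.40, 0.10, 0.20, 0.30),
                           p_beta = c(0.10, 0.40, 0.20, 0.30))) {
  spec <- synthetic_spec(n_frames = n_frames, seed = seed,
                         propensities = propensities)
  sys <- build_toy_system(spec)
  traj <- simulate_flooding(sys$topology, spec)
  list(spec = spec, topology = sys$topology, ground_truth = sys$ground_truth,
       trajectory = traj)
}
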