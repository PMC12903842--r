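test_that("tracks report relative z and programmed paths exactly", {
  mf <- toy_membrane()
  spec <- synthetic_spec(
    n_ligands_alpha = 2, n_ligands_beta = 1, n_frames = 50, sigma_res_A = 0.2,
    paths = list(list(species = "alpha", copy = 1L,
                      waypoints = data.frame(frame = c(1, 50), x = 0, y = 0,
                                             z = c(30, -30)))),
    seed = 3)
  sys <- build_toy_system(spec)
  traj <- simulate_flooding(sys$topology, spec)
  tracks <- ligand_tracks(traj, sys$ground_truth$membrane)
  expect_equal(sort(unique(tracks$resno)), c(101L, 102L, 103L))
  prog <- tracks[tracks$resno == 101L, ]
  want_z <- seq(30, -30, length.out = 50)
  expect_equal(prog$z_A, want_z, tolerance = 1e-6)
  expect_equal(prog$lateral_A, rep(0, 50), tolerance = 1e-6)

  only_beta <- ligand_tracks(traj, mf, species = "beta")
  expect_equal(unique(only_beta$species), "beta")
  expect_warning(
    ligand_tracks(simulate_flooding(sys$topology, spec), mf, species = character(0)),
    "no ligands")
})

test_that("constructed in-pore runs give the expected durations and merging", {
  dt <- 0.1
  z <- rep(30, 50)
  z[10:29] <- 0                      # 20 frames in pore
  tracks <- make_tracks(z, dt = dt)
  ev <- detect_residency_events(tracks, toy_membrane(), gap_tolerance_ns = 0)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 10)
  expect_equal(ev$end_frame, 29)
  expect_equal(ev$duration_ns, 2.0)

  # two runs separated by one out-of-pore frame merge under 0.2 ns tolerance
  z2 <- rep(30, 30)
  z2[5:10] <- 0; z2[12:20] <- 0
  t2 <- make_tracks(z2, dt = dt)
  merged <- detect_residency_events(t2, toy_membrane(), gap_tolerance_ns = 0.2)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start_frame, 5)
  expect_equal(merged$end_frame, 20)
  expect_equal(merged$n_frames_in_state, 15)
  unmerged <- detect_residency_events(t2, toy_membrane(), gap_tolerance_ns = 0)
  expect_equal(nrow(unmerged), 2)
  # events tile: in-state frames are conserved across merging
  expect_equal(sum(unmerged$n_frames_in_state), sum(merged$n_frames_in_state))
})

test_that("duration filtering is strict by default and reports exclusions", {
  ev <- data.frame(ligand = "L:101", resno = 101L, species = "alpha",
                   location = "pore", start_frame = 1L, end_frame = 1L,
                   n_frames_span = 1L, n_frames_in_state = 1L,
                   start_ns = 0, end_ns = 0,
                   duration_ns = c(1.5, 4.0, 4.1, 12.0))
  kept <- filter_events(ev, min_duration_ns = 4, strict = TRUE)
  expect_equal(kept$duration_ns, c(4.1, 12.0))
  rep_ <- attr(kept, "exclusion_report")
  expect_equal(rep_$excluded_fraction, 0.5)
  expect_equal(rep_$excluded_lt2ns_fraction, 0.5)  # 1.5 of {1.5, 4.0}
  expect_equal(unique(kept$cumulative_ns), sum(ev$duration_ns))

  lax <- filter_events(ev, min_duration_ns = 4, strict = FALSE)
  expect_equal(lax$duration_ns, c(4.0, 4.1, 12.0))

  empty <- filter_events(ev[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(is.na(attr(empty, "exclusion_report")$excluded_fraction))

  # monotonicity: raising the threshold never adds survivors
  for (thr in c(0, 2, 4, 5, 13)) {
    expect_true(all(filter_events(ev, thr)$duration_ns %in% kept$duration_ns |
                    thr <= 4))
  }
})

test_that("extramembranous-contact events follow the hydrogen-bond presence", {
  fx <- toy_flooding(n_frames = 800, seed = 23,
                     propensities = data.frame(resno = 20L, p_alpha = 0.9,
                                               p_beta = 0))
  mf <- fx$ground_truth$membrane
  ct <- hbond_timeseries(fx$trajectory)
  regions <- residue_regions(fx$trajectory, mf)
  expect_equal(unname(regions["A:20"]), "extracellular")
  tracks <- ligand_tracks(fx$trajectory, mf)
  ev <- detect_residency_events(tracks, mf, contacts = ct, regions = regions,
                                gap_tolerance_ns = 0.5)
  contact_ev <- ev[ev$location == "extramembranous_contact", ]
  expect_gt(nrow(contact_ev), 0)
  expect_equal(unique(contact_ev$species), "alpha")
  # presence conservation between the contact table and the events
  bound_frames <- unique(ct$events$frame[ct$events$protein_resid == "A:20"])
  expect_equal(sum(contact_ev$n_frames_in_state), length(bound_frames))

  bad <- hbond_timeseries(fx$trajectory, stride = 2)
  expect_error(detect_residency_events(tracks, mf, contacts = bad,
                                       regions = regions),
               class = "anomertraj_data_error")
})

test_that("programmed permeation events are recovered within one frame", {
  spec <- synthetic_spec(
    n_ligands_alpha = 3, n_ligands_beta = 3, n_frames = 200,
    paths = list(
      list(species = "alpha", copy = 1L,
           waypoints = data.frame(frame = c(1, 200), x = 0, y = 0,
                                  z = c(34, -34))),
      list(species = "beta", copy = 2L,
           waypoints = data.frame(frame = c(1, 100, 200), x = 0, y = 0,
                                  z = c(30, 0, 30)))),
    seed = 4)
  sys <- build_toy_system(spec)
  traj <- simulate_flooding(sys$topology, spec)
  mf <- sys$ground_truth$membrane
  tracks <- ligand_tracks(traj, mf)
  ev <- detect_residency_events(tracks, mf, gap_tolerance_ns = 0)
  prog <- sys$ground_truth$programmed_events
  expect_equal(nrow(prog), 2)
  for (k in seq_len(nrow(prog))) {
    resno <- 100L + if (prog$species[k] == "alpha") prog$copy[k] else
      spec$n_ligands_alpha + prog$copy[k]
    got <- ev[ev$resno == resno & ev$location == "pore", ]
    expect_equal(nrow(got), 1)
    expect_lte(abs(got$start_frame - prog$start_frame[k]), 1)
    expect_lte(abs(got$end_frame - prog$end_frame[k]), 1)
  }

  # transit accounting: one full permeation (alpha), one retreat (beta);
  # restricted to the programmed copies so free walkers cannot contribute
  kept <- filter_events(ev[ev$resno %in% c(101L, 105L), ], 4)
  ts <- pore_transit_summary(kept, tracks)
  expect_equal(ts$n_entries[ts$species == "alpha"], 1)
  expect_equal(ts$n_exits[ts$species == "alpha"], 1)
  expect_equal(ts$n_permeations[ts$species == "alpha"], 1)
  expect_equal(ts$n_entries[ts$species == "beta"], 1)
  expect_equal(ts$n_exits[ts$species == "beta"], 0)
  expect_equal(ts$n_permeations[ts$species == "beta"], 0)
})
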