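rotation_z <- function(th) {
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

test_that("superposition removes rigid motions exactly", {
  set.seed(5)
  ref <- matrix(rnorm(60, sd = 5), 20, 3)
  sp0 <- superpose(ref, ref)
  expect_equal(sp0$rmsd_A, 0, tolerance = 1e-12)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-9)

  moved <- ref %*% t(rotation_z(pi / 2)) + rep(c(5, 5, 5), each = 20)
  sp <- superpose(moved, ref)
  expect_lt(sp$rmsd_A, 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)

  expect_error(superpose(ref[1:2, ], ref[1:2, ]), class = "anomertraj_data_error")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear", class = "anomertraj_data_error")
})

test_that("fit rmsd matches the independent bio3d reference", {
  set.seed(6)
  ref <- matrix(rnorm(60, sd = 5), 20, 3)
  mob <- ref %*% t(rotation_z(0.8)) + rep(c(3, -2, 7), each = 20) +
    matrix(rnorm(60, sd = 0.3), 20, 3)
  ours <- superpose(mob, ref)$rmsd_A
  fitted <- suppressWarnings(bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(mob))))
  theirs <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - ref)^2)))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("fitted rmsd never exceeds unfitted rmsd", {
  set.seed(7)
  for (i in 1:20) {
    ref <- matrix(rnorm(36, sd = 4), 12, 3)
    mob <- ref + matrix(rnorm(36, sd = runif(1, 0.1, 3)), 12, 3)
    unfitted <- sqrt(mean(rowSums((mob - ref)^2)))
    expect_lte(superpose(mob, ref)$rmsd_A, unfitted + 1e-12)
  }
})

test_that("rmsf hand cases: static zero and a two-frame displacement", {
  topo <- make_ca_topology(4)
  static <- as_trajectory(topo, matrix(rep(rnorm(12), 5), 5, 12, byrow = TRUE), 0.1)
  expect_equal(unname(rmsf(static, 1:4, fit = FALSE)$rmsf_A), rep(0, 4))
  expect_equal(unname(rmsf(static, 1:4, fit = TRUE)$rmsf_A), rep(0, 4),
               tolerance = 1e-9)

  base <- matrix(c(0, 0, 0,  10, 0, 0,  0, 10, 0,  0, 0, 10), 1)
  xyz <- rbind(base, base)
  xyz[2, 1] <- 2  # atom 1 moves (0,0,0) -> (2,0,0)
  two <- as_trajectory(topo, xyz, 0.1)
  vals <- rmsf(two, 1:4, fit = FALSE)$rmsf_A
  expect_equal(unname(vals), c(1, 0, 0, 0))
  expect_error(rmsf(two, 1:4, window_ns = c(0, 0.1)), class = "anomertraj_data_error")
})

test_that("isotropic Gaussian jitter gives RMSF near sigma * sqrt(3)", {
  sigma <- 0.5
  n_frames <- 4000
  topo <- make_ca_topology(30)
  set.seed(8)
  base <- rep(rnorm(90, sd = 10), each = n_frames)
  xyz <- matrix(base + rnorm(n_frames * 90, sd = sigma), n_frames, 90)
  traj <- as_trajectory(topo, xyz, 0.1)
  vals <- rmsf(traj, 1:30, fit = FALSE)$rmsf_A
  expect_equal(mean(vals), sigma * sqrt(3), tolerance = 0.03)
})

test_that("window tiling: counts are floor(span/len) and moments concatenate", {
  topo <- make_ca_topology(3)
  n_frames <- 1000                       # 100 ns at dt = 0.1
  traj <- as_trajectory(topo, matrix(rnorm(n_frames * 9), n_frames, 9), 0.1)
  m <- sliding_window_rmsf(traj, 1:3, 25, fit = FALSE)
  expect_equal(ncol(m$values), 4)
  expect_message(sliding_window_rmsf(traj, 1:3, 30, fit = FALSE), "dropping")
  expect_error(sliding_window_rmsf(traj, 1:3, 200, fit = FALSE),
               class = "anomertraj_data_error")

  # zero-mean alternating pattern: window msf concatenates to full-span msf
  xyz <- matrix(rep(c(1, -1), length.out = n_frames), n_frames, 9)
  alt <- as_trajectory(topo, xyz, 0.1)
  full <- rmsf(alt, 1:3, fit = FALSE)$rmsf_A
  wins <- sliding_window_rmsf(alt, 1:3, 25, fit = FALSE)$values
  expect_equal(unname(sqrt(rowMeans(wins^2))), unname(full), tolerance = 1e-12)
})

test_that("fit-enabled RMSF is invariant under a global rigid motion", {
  fx <- toy_flooding(n_frames = 60, seed = 17)
  ca <- which(fx$topology$atoms$elety == "CA")
  v0 <- rmsf(fx$trajectory, ca, fit = TRUE)$rmsf_A
  R <- rotation_z(1.1)
  shift <- c(20, -30, 12)
  moved <- fx$trajectory
  for (i in seq_len(nrow(moved$xyz))) {
    fr <- frame_coords(moved, i) %*% t(R) + rep(shift, each = nrow(fx$topology$atoms))
    moved$xyz[i, ] <- as.vector(t(fr))
  }
  v1 <- rmsf(moved, ca, fit = TRUE)$rmsf_A
  expect_equal(v1, v0, tolerance = 1e-9)
})

test_that("difference maps subtract elementwise with the A-minus-B sign", {
  topo <- make_ca_topology(5)
  mk <- function(seed, label) {
    set.seed(seed)
    traj <- as_trajectory(topo, matrix(rnorm(200 * 15), 200, 15), 0.1)
    sliding_window_rmsf(traj, 1:5, 5, fit = FALSE, condition = label)
  }
  A <- mk(1, "alpha"); B <- mk(2, "beta")
  d <- rmsf_difference(A, B)
  expect_equal(d$values, A$values - B$values)
  expect_equal(rmsf_difference(B, A)$values, -d$values)
  expect_equal(rmsf_difference(A, A)$values, matrix(0, 5, 4,
               dimnames = dimnames(A$values)))
  short <- A; short$values <- A$values[, 1:2]
  expect_error(rmsf_difference(A, short), class = "anomertraj_data_error")
})

test_that("pair distance series equals brute-force pair minima", {
  topo <- make_ca_topology(5)
  xyz <- matrix(rnorm(40 * 15, sd = 6), 40, 15)
  traj <- as_trajectory(topo, xyz, 0.1)
  ts <- pair_distance_timeseries(traj, 1:2, 3:5)
  for (f in c(1, 17, 40)) {
    coords <- frame_coords(traj, f)
    d <- outer(1:2, 3:5, Vectorize(function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))))
    expect_equal(ts$distance_A[f], min(d), tolerance = 1e-12)
  }
  # two static atoms 4 A apart give a constant series
  xyz2 <- matrix(rep(c(0, 0, 0, 4, 0, 0, 9, 9, 9, 9, 9, 9, 9, 9, 9), 3), 3, 15,
                 byrow = TRUE)
  ts2 <- pair_distance_timeseries(as_trajectory(topo, xyz2, 0.1), 1, 2)
  expect_equal(ts2$distance_A, rep(4, 3))
  expect_error(pair_distance_timeseries(traj, integer(0), 1),
               class = "anomertraj_data_error")
})

test_that("breathing motion extremes are recovered in the distance monitor", {
  topo <- make_ca_topology(2)
  t_ns <- (0:199) * 0.1
  gap <- 4 + 1 * sin(2 * pi * t_ns / 5)   # amplitude 1 A around 4 A
  xyz <- cbind(0, 0, 0, gap, 0, 0)
  ts <- pair_distance_timeseries(as_trajectory(topo, xyz, 0.1), 1, 2)
  expect_equal(min(ts$distance_A), min(gap), tolerance = 1e-6)
  expect_equal(max(ts$distance_A), max(gap), tolerance = 1e-6)
})
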