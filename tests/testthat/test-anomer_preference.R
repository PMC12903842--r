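test_that("ratio classification matches the printed inclusive thresholds", {
  th <- preference_thresholds()
  expect_equal(preference_ratio(14, 10, th),
               data.frame(ratio = 1.4, classification = "alpha"))
  expect_equal(preference_ratio(7, 10, th),
               data.frame(ratio = 0.7, classification = "beta"))
  expect_equal(preference_ratio(5, 5, th),
               data.frame(ratio = 1.0, classification = "none"))
  expect_equal(preference_ratio(12, 0, th),
               data.frame(ratio = Inf, classification = "alpha"))
  expect_equal(preference_ratio(3, 2, th),
               data.frame(ratio = 1.5, classification = "insufficient"))
  expect_error(preference_thresholds(alpha_min_ratio = 0.5, beta_max_ratio = 0.7),
               class = "anomertraj_config_error")
})

test_that("species swap maps ratios to reciprocals and swaps labels", {
  th <- preference_thresholds()
  set.seed(99)
  n_a <- rpois(1000, 12)
  n_b <- rpois(1000, 12)
  fwd <- preference_ratio(n_a, n_b, th)
  rev <- preference_ratio(n_b, n_a, th)
  finite <- n_a > 0 & n_b > 0
  expect_equal(rev$ratio[finite], 1 / fwd$ratio[finite], tolerance = 1e-12)
  swap <- c(alpha = "beta", beta = "alpha", none = "none",
            insufficient = "insufficient")
  # the published cutoffs are not reciprocal (1/1.4 != 0.7), so the label
  # swap cannot hold inside the asymmetric boundary bands; it must hold
  # everywhere else
  in_band <- (fwd$ratio >= th$alpha_min_ratio & fwd$ratio < 1 / th$beta_max_ratio) |
             (fwd$ratio > th$beta_max_ratio & fwd$ratio <= 1 / th$alpha_min_ratio)
  expect_equal(rev$classification[!in_band],
               unname(swap[fwd$classification[!in_band]]))
  # with reciprocal thresholds the swap is exact on every pair
  th_sym <- preference_thresholds(alpha_min_ratio = 1.4, beta_max_ratio = 1 / 1.4)
  fwd2 <- preference_ratio(n_a, n_b, th_sym)
  rev2 <- preference_ratio(n_b, n_a, th_sym)
  expect_equal(rev2$classification, unname(swap[fwd2$classification]))
})

test_that("region assignment follows the slab/pore geometry", {
  mf <- toy_membrane(half = 15, pore = 10)
  expect_equal(assign_region(20, 0, mf), "extracellular")
  expect_equal(assign_region(-20, 0, mf), "intracellular")
  expect_equal(assign_region(0, 3, mf), "pore")
  expect_equal(assign_region(0, 12, mf), "other")
  expect_equal(assign_region(15, 3, mf), "pore")  # slab boundary is inclusive
})

test_that("preference table recovers programmed propensities and regions", {
  fx <- toy_flooding(n_frames = 2000, seed = 31)
  ct <- hbond_timeseries(fx$trajectory)
  regions <- residue_regions(fx$trajectory, fx$ground_truth$membrane)
  pref <- build_preference_table(ct, regions)
  expect_equal(pref$residue, c("A:2", "A:5", "A:8", "A:20"))  # resno order
  get <- function(r) pref[pref$resno == r, ]
  expect_equal(get(2)$classification, "alpha")   # rho = 4
  expect_equal(get(5)$classification, "beta")    # rho = 0.25
  expect_equal(get(8)$classification, "none")    # rho = 1
  expect_equal(get(2)$region, "intracellular")
  expect_equal(get(8)$region, "pore")
  expect_equal(get(20)$region, "extracellular")

  rs <- region_summary(pref)
  expect_equal(rs$n_alpha_pref[rs$region == "intracellular"], 1)
  expect_equal(rs$n_beta_pref[rs$region == "intracellular"], 1)
  expect_equal(rs$n_none[rs$region == "pore"], 1)
  expect_equal(sum(rs[, c("n_alpha_pref", "n_beta_pref", "n_none")]),
               sum(pref$classification != "insufficient"))
})

test_that("single-species tables trigger the degeneracy warning", {
  fx <- toy_flooding(n_frames = 400, seed = 41,
                     propensities = data.frame(resno = 2L, p_alpha = 0.5,
                                               p_beta = 0))
  ct <- hbond_timeseries(fx$trajectory)
  expect_warning(build_preference_table(ct), "degenerate")
})

test_that("relabelling species swaps table classifications symmetrically", {
  fx <- toy_flooding(n_frames = 1200, seed = 51)
  ct <- hbond_timeseries(fx$trajectory)
  pref <- suppressWarnings(build_preference_table(ct))
  # swap the species column wholesale (equivalent to swapping the name map)
  ct2 <- ct
  ct2$counts$species <- c(alpha = "beta", beta = "alpha")[ct2$counts$species]
  pref2 <- suppressWarnings(build_preference_table(ct2))
  finite <- is.finite(pref$ratio) & pref$ratio > 0
  expect_equal(pref2$ratio[finite], 1 / pref$ratio[finite], tolerance = 1e-12)
  swap <- c(alpha = "beta", beta = "alpha", none = "none",
            insufficient = "insufficient")
  expect_equal(pref2$classification, unname(swap[pref$classification]))
})

test_that("proportion shifts: identity gives zero, share sums are 1", {
  fx <- toy_flooding(n_frames = 1000, seed = 61)
  ct <- hbond_timeseries(fx$trajectory)
  ps <- proportion_shift(ct, ct, "alpha")
  expect_equal(ps$delta, rep(0, nrow(ps)))
  expect_false(any(ps$flagged_cooperative))
  expect_equal(sum(ps$share_mixed), 1, tolerance = 1e-12)
  expect_equal(sum(ps$share_single), 1, tolerance = 1e-12)
})

test_that("a halved mixed-condition propensity yields a negative flagged shift", {
  base_p <- data.frame(resno = c(2L, 5L), p_alpha = c(0.4, 0.4), p_beta = c(0, 0))
  half_p <- data.frame(resno = c(2L, 5L), p_alpha = c(0.2, 0.4), p_beta = c(0, 0))
  single <- toy_flooding(n_frames = 2500, seed = 71, propensities = base_p)
  mixed <- toy_flooding(n_frames = 2500, seed = 72, propensities = half_p)
  ct_single <- hbond_timeseries(single$trajectory)
  ct_mixed <- hbond_timeseries(mixed$trajectory)
  ps <- proportion_shift(ct_mixed, ct_single, "alpha")
  r2 <- ps[ps$resno == 2, ]
  # share drops from ~1/2 toward ~1/3
  expect_lt(r2$delta, -0.02)
  expect_true(r2$flagged_cooperative)
})

test_that("a species absent from one condition is a degenerate-condition error", {
  fx <- toy_flooding(n_frames = 300, seed = 81,
                     propensities = data.frame(resno = 2L, p_alpha = 0.5, p_beta = 0))
  ct <- hbond_timeseries(fx$trajectory)
  expect_error(proportion_shift(ct, ct, "beta"),
               class = "anomertraj_data_error")
})
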