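test_that("trajectories honour the pattern envelopes", {
  for (s in 1:8) {
    t2 <- simulate_trajectory(2, 120, seed = s)
    expect_lte(max(t2$srba_env), 200)
    expect_gte(min(t2$srba_env), 0)
    expect_true(is.na(t2$shift_fraction))
    t1 <- simulate_trajectory(1, 120, seed = s, env_noise = 0)
    expect_gte(max(t1$srba_env), 600)
    expect_lte(max(t1$srba_env), 1200)
    expect_lt(t1$srba_env[t1$n_points], 400)
    expect_lte(t1$srba_env[1], 200)
    # monotone rise up to the peak, then a fall below 400 (noise-free)
    i_peak <- which.max(t1$srba_env)
    expect_true(all(diff(t1$srba_env[1:i_peak]) >= -1e-9))
    f <- seq(0, 1, length.out = t1$n_points)
    after <- t1$srba_env[f > t1$shift_fraction + 0.05]
    expect_true(all(after < 400))
    # Pattern-1 Pb rises terminally; Pattern-2 Pb elevated at the focus
    expect_gt(mean(t1$pb_env[f > 0.95]), mean(t1$pb_env[f < 0.5]))
    t2s <- simulate_trajectory(2, 120, seed = s, env_noise = 0)
    expect_gt(t2s$pb_env[1], mean(t2s$pb_env[f > 0.5]))
  }
  expect_equal(simulate_trajectory(1, 50, seed = 1)$n_points, 50)
  expect_error(simulate_trajectory(3, 100), "pattern")
  expect_error(simulate_trajectory(1, 20), "n_points")
})

test_that("rendered blanks sit at the configured baseline and the noiseless
          plateau is exactly sensitivity x drift x ppm", {
  config <- mass_config()
  instr <- instrument_model(config, seed = 5)
  b <- render_ablation("gas_blank", config = config, instrument = instr,
                       order = 1, n_orders = 10, noise = 1, seed = 5,
                       record_id = "b")
  n <- nrow(b$cps)
  for (el in c("Ca43", "Sr88", "U238")) {
    se <- sd(b$cps[, el]) / sqrt(n)
    expect_lt(abs(mean(b$cps[, el]) - instr$blank_mean[[el]]), 3.3 * se)
  }
  ppm <- c(Sr88 = 1000, Ba137 = 2)
  s <- render_ablation("spot", ppm, config, instr, order = 4, n_orders = 10,
                       noise = 0, spike_prob = 0, seed = 5, record_id = "s")
  sig <- s$time_s >= s$signal_window_s[1] & s$time_s <= s$signal_window_s[2]
  d <- 1 + instr$drift_slope[["Sr88"]] * 3 / 9
  expect_equal(unique(s$cps[sig, "Sr88"]),
               instr$blank_mean[["Sr88"]] + instr$sensitivity[["Sr88"]] * d * 1000)
  # 60 s plateau at 5 points/s
  expect_equal(sum(sig), 300)
})

test_that("a 10% drift slope makes the last standard read about 1.10x the
          first, per mass", {
  config <- mass_config()
  instr <- instrument_model(config, seed = 1)
  instr$drift_slope[] <- 0.10
  nist <- stats::setNames(config$isotopes$nist612_ppm, config$isotopes$label)
  first <- render_ablation("nist612", nist, config, instr, order = 1,
                           n_orders = 11, noise = 0, spike_prob = 0,
                           seed = 1, record_id = "n1")
  last <- render_ablation("nist612", nist, config, instr, order = 11,
                          n_orders = 11, noise = 0, spike_prob = 0,
                          seed = 1, record_id = "n2")
  sig <- function(r) r$time_s >= r$signal_window_s[1] &
    r$time_s <= r$signal_window_s[2]
  for (el in c("Sr88", "Pb208")) {
    net1 <- mean(first$cps[sig(first), el]) - instr$blank_mean[[el]]
    net2 <- mean(last$cps[sig(last), el]) - instr$blank_mean[[el]]
    expect_equal(net2 / net1, 1.10, tolerance = 1e-10)
  }
})

test_that("make_study reproduces the sampling design and is seed-stable", {
  st <- make_study(study_design(seed = 7))
  man <- st$run$manifest
  expect_equal(nrow(st$specimens), 4 + 14 + 15)
  expect_equal(sum(st$specimens$class == "embryo"), 14)
  # 14 embryo focus spots with 3 replicates each
  foc <- man[man$role == "spot" & man$target == "focus" &
               grepl("^E", man$specimen_id), ]
  expect_equal(nrow(foc), 42)
  expect_true(all(table(foc$specimen_id) == 3))
  # acquisition order is total and unique
  expect_equal(sort(man$order), seq_len(nrow(man)))
  # gas blanks bracket every ablation
  abl <- which(man$role != "gas_blank")
  expect_true(all(man$role[abl - 1] == "gas_blank"))
  # standards present as replicate pairs
  expect_true(all(table(man$std_bracket[man$role == "nist612"]) == 2))
  # exactly 11 of 15 YOY truths are Pattern 1
  expect_equal(sum(st$truth$yoy_pattern == 1), 11)
  # determinism: same design, same seed, byte-identical cps
  st2 <- make_study(study_design(seed = 7))
  expect_identical(st$run$manifest, st2$run$manifest)
  expect_identical(st$run$records[["T_Y07"]]$cps,
                   st2$run$records[["T_Y07"]]$cps)
  expect_identical(st$truth$yoy_pattern, st2$truth$yoy_pattern)
})

test_that("a design without YOY yields no YOY transects, and invalid designs
          are rejected", {
  st <- make_study(study_design(n_females = 2, litter_sizes = c(2, 2),
                                n_yoy = 0, seed = 3),
                   noise = 0, spike_prob = 0, replicate_sd_log = 0)
  man <- st$run$manifest
  expect_false(any(grepl("^Y", man$specimen_id[man$role == "transect"])))
  expect_error(study_design(pattern_mix = 1.5), "pattern_mix")
  expect_error(study_design(n_females = 2, litter_sizes = c(2, 2),
                            embryo_length_range = c(49, 41)))
})

test_that("a mother's edge-period environment equals her embryos' exactly,
          and Sr:Ca / Ba:Ca are inversely related along transects", {
  st <- tiny_noiseless_study()
  # F01 and her embryos E01, E02 share the litter-1 edge environment
  f_edge <- st$truth$records[["S_F01_edge_1"]]$true_ppm
  for (id in c("S_E01_edge_1", "S_E02_edge_2")) {
    expect_identical(st$truth$records[[id]]$true_ppm, f_edge)
  }
  tr <- st$truth$mother_trajectories[[1]]
  expect_equal(tr$pattern, 1L) # gestating mothers make the offshore excursion
  p <- st$truth$records[["T_E01"]]$true_ppm
  expect_lt(cor(p[, "Sr88"], p[, "Ba137"], method = "spearman"), 0)
})
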