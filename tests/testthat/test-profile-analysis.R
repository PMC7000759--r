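test_that("ratio profiles divide point-wise and flag nonpositive
          denominators as missing", {
  st <- tiny_noiseless_study()
  model <- build_drift_model(st$run)
  p <- reduce_transect(st$run$records[["T_Y02"]], st$run, model)
  rp <- ratio_profiles(p)
  i <- 25
  expect_equal(rp$srba[i], p$cps[i, "Sr88"] / p$cps[i, "Ba137"],
               ignore_attr = TRUE)
  expect_equal(rp$pbca[i], p$cps[i, "Pb208"] / p$cps[i, "Ca43"],
               ignore_attr = TRUE)
  # zero denominator -> missing, never infinite
  p2 <- p
  p2$cps[10, "Ba137"] <- 0
  rp2 <- ratio_profiles(p2)
  expect_true(is.na(rp2$srba[10]))
  expect_false(any(is.infinite(rp2$srba)))
  p3 <- p
  p3$cps <- p3$cps[, c("Sr88", "Ca43")]
  expect_error(ratio_profiles(p3), "lacks required masses")
})

test_that("the running average shrinks symmetrically at the edges,
          preserves constants, and is shift-equivariant", {
  x <- c(0, 0, 0, 11, 0, 0, 0, 0, 0, 0, 0)
  sm <- moving_average(x, 11)
  expect_equal(sm[6], 1)          # the only full-window position
  expect_equal(sm[4], 11 / 7)     # window shrinks to 7 points at i = 4
  expect_equal(sm[1], 0)
  expect_equal(moving_average(rep(4.2, 30), 11), rep(4.2, 30))
  expect_identical(moving_average(1:7 * 1.0, 1), 1:7 * 1.0)
  set.seed(2)
  y <- rnorm(60)
  expect_equal(moving_average(y + 3, 11), moving_average(y, 11) + 3)
  expect_error(moving_average(y, 10), "odd")
  # missing points are excluded from window means
  y[5] <- NA
  expect_false(any(is.na(moving_average(y, 11)[-5])))
})

test_that("the threshold rules call flat-low profiles Pattern 2,
          peak-and-return profiles Pattern 1, and the gap undetermined", {
  n <- 100
  flat <- fake_ratio_profile(rep(150, n), pbca = c(rep(2, 10), rep(1, 90)))
  c2 <- classify_pattern(flat)
  expect_equal(c2$pattern, 2L)
  expect_true(is.na(c2$r_t_um))
  expect_true(c2$pb_corroborated) # elevated Pb at the focus

  up_down <- c(seq(100, 900, length.out = 85), seq(900, 100, length.out = 15))
  pb <- c(rep(0.4, 85), rep(1.5, 15))
  c1 <- classify_pattern(fake_ratio_profile(up_down, pb))
  expect_equal(c1$pattern, 1L)
  expect_false(is.na(c1$r_t_um))
  expect_gte(c1$peak_srba, c1$terminal_srba)
  expect_true(c1$pb_corroborated)

  mid <- fake_ratio_profile(c(seq(100, 450, length.out = 50),
                              seq(450, 100, length.out = 50)))
  cm <- classify_pattern(mid)
  expect_true(is.na(cm$pattern))

  expect_error(classify_pattern(fake_ratio_profile(rep(NA_real_, 100))),
               "missing")
  expect_error(classify_pattern(fake_ratio_profile(rep(100, 30))), "short")
})

test_that("the shift point is the first sub-threshold crossing after the
          maximum, read off an independently constructed series", {
  # peak 900 at 300 um; the smoothed series drops below 400 at 540 um
  d <- seq(2, 800, by = 2)
  s <- numeric(length(d))
  s[d <= 300] <- 100 + (900 - 100) * (d[d <= 300] / 300)
  s[d > 300] <- 900 - (d[d > 300] - 300) * 500 / 239
  rp <- fake_ratio_profile(s, distance = d)
  i_oracle <- which(d > 300 & s < 400)[1]
  expect_equal(d[i_oracle], 540)
  expect_equal(detect_shift(rp), 540)
  # threshold above the global maximum -> no crossing, an error
  expect_error(detect_shift(rp, pattern_thresholds(t_return = 2000,
                                                   t_peak = 2100)),
               "crossing")
})

test_that("shift detection is invariant to a uniform rescale of both Sr and
          Ba and matches the generator truth noiselessly", {
  s <- simulate_transect(1, noise = 0, spike_prob = 0, env_noise = 0,
                         seed = 33)
  p <- s$profile
  rp <- ratio_profiles(p)
  call <- classify_pattern(rp)
  expect_equal(call$pattern, 1L)
  est <- call$r_t_um / max(p$distance_um)
  expect_lte(abs(est - s$trajectory$shift_fraction), 0.05)
  # scale Sr and Ba cps together: identical call
  p2 <- p
  p2$cps[, c("Sr88", "Ba137")] <- p2$cps[, c("Sr88", "Ba137")] * 3.7
  expect_equal(detect_shift(ratio_profiles(p2)), call$r_t_um)
})

test_that("the focus Pb:Ca rank-sum utility matches exhaustive enumeration
          in the extreme cases", {
  set.seed(6)
  a <- runif(6, 1, 2)
  expect_gt(suppressWarnings(compare_focus_pb(a, a)$p.value), 0.9)
  b <- a * 10
  expect_lte(compare_focus_pb(b[1:4], a[1:4])$p.value, 0.05)
  # exact two-group enumeration for n = 4 vs 4: minimal p = 2/choose(8,4)
  expect_equal(compare_focus_pb(b[1:4], a[1:4])$p.value, 2 / 70)
  expect_warning(res11 <- compare_focus_pb(1.3, 2.4), "uninformative")
  expect_equal(res11$p.value, 1)
  expect_error(compare_focus_pb(numeric(0), a), "nonempty")
})
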