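test_that("Grubbs decisions match the closed-form oracle and despiking
          replaces spikes with the clean mean", {
  # hand oracle: G = max|x - mean|/sd vs t-based critical value
  g_stat <- function(x) max(abs(x - mean(x))) / sd(x)
  g_crit <- function(n, a = 0.05) {
    t <- qt(1 - a / (2 * n), n - 2)
    ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
  }
  expect_equal(grubbs_critical(5), g_crit(5), tolerance = 1e-12)
  expect_equal(round(g_crit(5), 3), 1.715)

  x <- c(10, 10, 10, 10, 100)
  expect_gt(g_stat(x), g_crit(5)) # 1.789 > 1.715
  d <- despike_grubbs(x)
  expect_equal(d$series, rep(10, 5))
  expect_equal(d$spikes, 5L)

  expect_equal(despike_grubbs(rep(10, 5))$spikes, integer(0))

  # accept/reject agreement with the oracle on random series
  set.seed(31)
  for (i in 1:25) {
    y <- rnorm(12)
    j <- sample(12, 1)
    y[j] <- y[j] + sample(c(0, 6), 1)
    first_reject <- g_stat(y) > g_crit(12)
    d <- despike_grubbs(y)
    expect_identical(length(d$spikes) > 0, first_reject)
    if (first_reject) expect_true(j %in% d$spikes)
  }
})

test_that("despiking is idempotent and leaves short series untouched", {
  set.seed(8)
  for (i in 1:10) {
    y <- rnorm(40)
    y[sample(40, 2)] <- y[sample(40, 2)] + 15
    once <- despike_grubbs(y)$series
    expect_identical(despike_grubbs(once)$series, once)
  }
  expect_warning(out <- despike_grubbs(c(1, 2)), "shorter")
  expect_identical(out$series, c(1, 2))
})

test_that("background subtraction is exact: blank-level records integrate to
          zero and a known plateau to its net height", {
  config <- mass_config()
  instr <- instrument_model(config, seed = 2)
  # spot whose plateau equals blank + 1000 on Sr88 via ppm = 1000/S
  run <- make_spot_run(list(sp_r1 = c(Sr88 = 1000 / instr$sensitivity[["Sr88"]])),
                       config, noise = 0, seed = 2, instrument = instr)
  rec <- run$records[["sp_r1"]]
  # neutralize drift so the plateau is exactly S * ppm
  instr0 <- instr
  instr0$drift_slope[] <- 0
  rec0 <- render_ablation("spot",
                          c(Sr88 = 1000 / instr$sensitivity[["Sr88"]],
                            Ca43 = 399000),
                          config, instr0, order = rec$order,
                          n_orders = max(run$manifest$order), noise = 0,
                          spike_prob = 0, seed = 2, record_id = "sp_r1",
                          specimen_id = "sp", target = "focus", replicate = 1)
  res <- integrate_signal(rec0, sharktrace:::bracketing_blanks(run, rec0),
                          config)
  expect_equal(res$net[["Sr88"]], 1000, tolerance = 1e-9)
  expect_equal(res$net[["Pb208"]], 0, tolerance = 1e-9)

  # a record that never leaves the blank level fails ablation
  blank_like <- run$records[["B01"]]
  blank_like$record_id <- "flat"
  expect_error(
    integrate_signal(blank_like, sharktrace:::bracketing_blanks(run, rec), config),
    class = "sharktrace_failed_ablation")
})

test_that("drift factors interpolate linearly between brackets and the LOD
          follows the 3 SD rule", {
  model <- structure(list(
    sensitivity = c(Sr88 = 50), bracket_order = c(0, 10),
    bracket_rel = matrix(c(1, 1.1), 2, 1, dimnames = list(NULL, "Sr88")),
    blank_mean = c(Sr88 = 200), blank_sd = c(Sr88 = 100),
    lod_ref_ppm = c(Sr88 = 6), uncalibratable = character(0),
    config = mass_config(), alpha = 0.05), class = "calibration_model")
  expect_equal(drift_at(model, 5)[["Sr88"]], 1.05)
  expect_equal(drift_at(model, -5)[["Sr88"]], 1)    # constant extrapolation
  expect_equal(drift_at(model, 99)[["Sr88"]], 1.1)
  expect_equal(lod_at(model, 0)[["Sr88"]], 3 * 100 / 50) # 6 ppm
  # monotonicity: larger blank SD -> larger LOD
  model2 <- model
  model2$blank_sd <- c(Sr88 = 200)
  expect_gt(lod_at(model2, 0)[["Sr88"]], lod_at(model, 0)[["Sr88"]])
})

test_that("drift correction exactly undoes the synthetic linear drift", {
  st <- tiny_noiseless_study()
  model <- build_drift_model(st$run)
  man <- st$run$manifest
  std <- man[man$role == "nist612", ]
  for (id in std$record_id) {
    rec <- st$run$records[[id]]
    res <- integrate_signal(rec, sharktrace:::bracketing_blanks(st$run, rec),
                            st$run$config)
    corrected <- res$net / drift_at(model, rec$order)
    expect_equal(corrected, model$sensitivity *
                   stats::setNames(st$run$config$isotopes$nist612_ppm,
                                   st$run$config$isotopes$label),
                 tolerance = 1e-9)
  }
})

test_that("noiseless spot quantification recovers truth to 1e-6 and obeys the
          internal-standard identity", {
  st <- tiny_noiseless_study()
  model <- build_drift_model(st$run)
  man <- st$run$manifest
  ids <- man$record_id[man$role == "spot" & man$specimen_id == "E01" &
                         man$target == "focus"]
  sig <- quantify_spot(st$run$records[ids], st$run, model)
  expect_equal(sig$ratio_umol_mol[sig$element == "Ca43"], 1e6)
  truth <- st$truth$litter_signatures[["litter1_focus"]]
  expect_equal(sig$ratio_umol_mol, unname(truth[sig$element]),
               tolerance = 1e-6)
  truth_ppm <- st$truth$records[[ids[1]]]$true_ppm
  expect_equal(sig$ppm, unname(truth_ppm[sig$element]), tolerance = 1e-6)
})

test_that("a sample ablated at the standard's composition returns the
          standard's molar ratios", {
  config <- mass_config()
  iso <- config$isotopes
  nist <- stats::setNames(iso$nist612_ppm, iso$label)
  run <- make_spot_run(list(std_r1 = nist), config, noise = 0, seed = 4)
  model <- build_drift_model(run)
  sig <- quantify_spot(run$records["std_r1"], run, model)
  a <- stats::setNames(iso$atomic_mass, iso$label)
  expected <- (nist / a) / (nist[["Ca43"]] / a[["Ca43"]]) * 1e6
  expect_equal(sig$ratio_umol_mol, unname(expected[sig$element]),
               tolerance = 1e-9)
})

test_that("outlyingness handles identical replicates, flags a gross
          displacement, and an infinite cutoff excludes nothing", {
  n <- 40
  base <- matrix(rep(c(10, 200, 5, 80), each = n), nrow = n)
  # identical replicates: every scale degenerates, nothing is excluded
  expect_warning(res0 <- detect_outlier_replicates(base), "degenerate")
  expect_length(res0$exclude, 0)
  set.seed(5)
  x <- base + matrix(rnorm(4 * n, 0, 1), n, 4)
  res <- detect_outlier_replicates(x, seed = 9)
  expect_lt(max(res$outlyingness), 10)
  # displace one replicate by 50 pooled MADs on one element
  x2 <- x
  x2[3, 2] <- x2[3, 2] + 50 * mad(x[, 2])
  res2 <- detect_outlier_replicates(x2, seed = 9)
  expect_gt(res2$outlyingness[3], 10)
  expect_equal(unname(res2$exclude), 3L)
  res3 <- detect_outlier_replicates(x2, cutoff = Inf, seed = 9)
  expect_length(res3$exclude, 0)
  expect_error(detect_outlier_replicates(x[1:3, ]), ">= 5")
})

test_that("the below-LOD rule drops elements at or above the 10% boundary", {
  sig <- data.frame(element = rep(c("A", "B", "C"), each = 20),
                    below_lod = c(rep(FALSE, 20),               # A: 0%
                                  rep(c(TRUE, FALSE), c(2, 18)), # B: 10%
                                  rep(c(TRUE, FALSE), c(9, 11))))# C: 45%
  res <- filter_by_lod(sig)
  expect_identical(res$retained, "A")
  expect_setequal(res$dropped$element, c("B", "C"))
  expect_true(all(res$signatures$element == "A"))
  all_bad <- data.frame(element = "A", below_lod = rep(TRUE, 5))
  expect_error(filter_by_lod(all_bad), "all elements")
})

test_that("transect reduction maps time to distance at the scan speed,
          recovers the truth profile noiselessly, and is orientation-aware", {
  st <- tiny_noiseless_study()
  model <- build_drift_model(st$run)
  rec <- st$run$records[["T_Y01"]]
  p <- reduce_transect(rec, st$run, model)
  # 10 um/s at 5 points/s -> 2 um per point, starting after the 2 s trim
  expect_equal(unique(round(diff(p$distance_um), 9)), 2)
  expect_equal(p$distance_um[1], 20)
  # the reduced ppm equal the rendered truth at the matching grid points
  truth <- st$truth$records[["T_Y01"]]$true_ppm
  trim <- 10 # 2 s x 5 points/s
  idx <- seq_len(p$n_points) + trim
  for (el in c("Sr88", "Ba137", "Mg24")) {
    expect_equal(p$ppm[, el], truth[idx, el], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # a distal-origin scan is reversed back onto the focus coordinate
  rec_rev <- rec
  rec_rev$scan_origin <- "distal"
  p_rev <- reduce_transect(rec_rev, st$run, model)
  expect_equal(p_rev$ppm[, "Sr88"], rev(p$ppm[, "Sr88"]), ignore_attr = TRUE)
  expect_true(all(diff(p_rev$distance_um) > 0))
})

test_that("resampling interpolates onto the longest grid and stacks the
          feature matrix as elements x points", {
  mk <- function(id, n, vals) {
    structure(list(specimen_id = id, record_id = id,
                   distance_um = seq(0, by = 2, length.out = n),
                   cps = matrix(vals, nrow = n,
                                dimnames = list(NULL, c("Sr88", "Ba137"))),
                   ppm = matrix(vals, nrow = n,
                                dimnames = list(NULL, c("Sr88", "Ba137"))),
                   n_points = n, resampled = FALSE),
              class = "transect_profile")
  }
  p3 <- mk("a", 3, c(0, 10, 20, 5, 5, 5))
  p5 <- mk("b", 5, c(seq(0, 40, 10), rep(1, 5)))
  res <- resample_transects(list(p3, p5), value = "ppm")
  expect_equal(res$n_points, 5)
  expect_equal(res$profiles[[1]]$ppm[, "Sr88"], c(0, 5, 10, 15, 20),
               ignore_attr = TRUE)
  expect_equal(dim(res$features), c(2, 10))
  expect_equal(unname(res$means["a", "Sr88"]), 10)
  # already equal-length profiles pass through unchanged
  res2 <- resample_transects(list(p5, p5), value = "ppm")
  expect_equal(res2$profiles[[1]]$ppm, p5$ppm, ignore_attr = TRUE)
  expect_error(resample_transects(list(p3)), "length")
})

test_that("full-chain recovery holds under default noise: < 5% relative RMSE
          per element over 30 spot signatures", {
  st <- make_study(study_design(seed = 19))
  model <- build_drift_model(st$run)
  sp <- reduce_spots(st$run, model)
  sig <- sp$all_signatures
  sig <- sig[!is.na(sig$ratio_umol_mol), ]
  truth_of <- function(spec, target) {
    if (grepl("^F", spec)) {
      l <- as.integer(sub("F0?", "", spec))
      return(st$truth$litter_signatures[[paste0("litter", l, "_", target)]])
    }
    if (grepl("^E", spec)) {
      litter <- rep(1:4, c(4, 3, 3, 4))[as.integer(sub("E0?", "", spec))]
      return(st$truth$litter_signatures[[paste0("litter", litter, "_", target)]])
    }
    st$truth$yoy_signatures[[paste0(spec, "_", target)]]
  }
  keys <- unique(sig[, c("specimen_id", "target")])
  expect_gte(nrow(keys), 30)
  rel_err <- sapply(seq_len(nrow(keys)), function(i) {
    s <- sig[sig$specimen_id == keys$specimen_id[i] &
               sig$target == keys$target[i], ]
    tr <- truth_of(keys$specimen_id[i], keys$target[i])
    (s$ratio_umol_mol - tr[s$element]) / tr[s$element]
  })
  rmse_by_el <- sqrt(rowMeans(rel_err^2))
  expect_true(all(rmse_by_el < 0.05))
})
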