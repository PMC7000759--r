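# Shared in-code fixtures. Everything is generated; nothing is read from disk.

# a minimal run: blanks + two NIST-612 pairs bracketing a set of spot
# ablations with known true ppm (list of named vectors, one per spot)
make_spot_run <- function(spot_ppm, config = mass_config(), noise = 0,
                          spike_prob = 0, seed = 1L,
                          instrument = instrument_model(config, seed)) {
  iso <- config$isotopes
  nist <- stats::setNames(iso$nist612_ppm, iso$label)
  # every spot needs the internal standard to form a detectable plateau
  spot_ppm <- lapply(spot_ppm, function(p) {
    if (!config$internal_standard %in% names(p)) {
      p <- c(p, stats::setNames(config$ca_mass_fraction * 1e6,
                                config$internal_standard))
    }
    p
  })
  n_spots <- length(spot_ppm)
  n_orders <- 2L * (4L + n_spots) + 1L
  recs <- list()
  oi <- 0L
  bi <- 0L
  emit <- function(role, ppm = NULL, id, ...) {
    oi <<- oi + 1L
    recs[[oi]] <<- render_ablation(role, ppm, config, instrument, oi,
                                   n_orders, noise, spike_prob, seed, id, ...)
  }
  blank <- function() {
    bi <<- bi + 1L
    emit("gas_blank", id = sprintf("B%02d", bi))
  }
  blank(); emit("nist612", nist, "N1_1", std_bracket = 1L)
  blank(); emit("nist612", nist, "N1_2", std_bracket = 1L)
  for (i in seq_len(n_spots)) {
    blank()
    emit("spot", spot_ppm[[i]], names(spot_ppm)[i],
         specimen_id = sub("_r[0-9]+$", "", names(spot_ppm)[i]),
         target = "focus", replicate = i)
  }
  blank(); emit("nist612", nist, "N2_1", std_bracket = 2L)
  blank(); emit("nist612", nist, "N2_2", std_bracket = 2L)
  blank()
  run_sequence(recs, config, root_seed = seed)
}

# a small noiseless study reused across reduction tests
tiny_noiseless_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_study(study_design(n_females = 2, litter_sizes = c(2, 2),
                                        n_yoy = 2, pattern_mix = 0.5,
                                        seed = 11),
                           noise = 0, spike_prob = 0, replicate_sd_log = 0)
    }
    cache
  }
})

# hand-built ratio profile for threshold-rule tests
fake_ratio_profile <- function(srba, pbca = rep(1, length(srba)),
                               distance = seq_along(srba) * 2) {
  structure(list(specimen_id = "fake", distance_um = distance,
                 srba = srba, pbca = pbca,
                 srba_smooth = srba, pbca_smooth = pbca, window = 1),
            class = "ratio_profile")
}
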