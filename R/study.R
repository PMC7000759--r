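#' Study design for the synthetic gestation-microchemistry experiment
#'
#' Encodes the sampling design being emulated: pregnant females with their
#' litters of near-term embryos (maternal-tag hypotheses) and free-swimming
#' young-of-the-year (YOY) whose vertebrae retain the complete in utero
#' record (migration-pattern hypothesis). Defaults reproduce the study
#' conditions: 4 females of 240-291 cm total length with litters of 4, 3, 3
#' and 4 embryos (41-49 cm), and 15 YOY of 49.2-59.6 cm across three nursery
#' sites, 11 of 15 mothers showing the offshore-excursion pattern.
#'
#' @param n_females number of pregnant females (= litters).
#' @param litter_sizes integer vector, embryos per litter (length `n_females`).
#' @param n_yoy number of young-of-the-year specimens.
#' @param pattern_mix fraction of YOY mothers with Pattern 1 (offshore
#'   excursion); the count is deterministic: `round(pattern_mix * n_yoy)`.
#' @param female_lengths total lengths (cm) of the females; default the four
#'   observed lengths when `n_females == 4`, otherwise drawn uniformly from
#'   `female_length_range`.
#' @param female_length_range,embryo_length_range,yoy_length_range length
#'   intervals (cm).
#' @param birth_length_range length-at-birth interval (cm) used to place the
#'   YOY birthmark radius.
#' @param n_sites number of YOY nursery sites (group labels only).
#' @param seed root seed; all generator randomness derives from it.
#' @return object of class `study_design`.
#' @export
study_design <- function(n_females = 4,
                         litter_sizes = c(4, 3, 3, 4),
                         n_yoy = 15,
                         pattern_mix = 11 / 15,
                         female_lengths = NULL,
                         female_length_range = c(240, 291),
                         embryo_length_range = c(41, 49),
                         yoy_length_range = c(49.2, 59.6),
                         birth_length_range = c(44, 53),
                         n_sites = 3,
                         seed = 1L) {
  stopifnot(n_females >= 1, length(litter_sizes) == n_females,
            all(litter_sizes >= 1), n_yoy >= 0)
  if (!(pattern_mix >= 0 && pattern_mix <= 1)) {
    stop("pattern_mix must be in [0, 1]")
  }
  for (rg in list(female_length_range, embryo_length_range, yoy_length_range,
                  birth_length_range)) {
    stopifnot(length(rg) == 2, rg[1] < rg[2])
  }
  if (is.null(female_lengths) && n_females == 4 &&
      identical(female_length_range, c(240, 291))) {
    female_lengths <- c(291, 277, 253, 240)
  }
  if (!is.null(female_lengths) && length(female_lengths) != n_females) {
    stop("female_lengths must have length n_females")
  }
  structure(list(n_females = n_females, litter_sizes = as.integer(litter_sizes),
                 n_yoy = as.integer(n_yoy), pattern_mix = pattern_mix,
                 female_lengths = female_lengths,
                 female_length_range = female_length_range,
                 embryo_length_range = embryo_length_range,
                 yoy_length_range = yoy_length_range,
                 birth_length_range = birth_length_range,
                 n_sites = n_sites, seed = as.integer(seed)),
            class = "study_design")
}

#' Instrument forward-model parameters
#'
#' Per-mass gas-blank baselines (cps), sensitivities (cps per ppm) and linear
#' sensitivity-drift slopes (fractional change over the whole run). These are
#' working defaults for a quadrupole ICP-MS, shared between the generator and
#' nothing else: the reducer re-estimates sensitivity and drift from the
#' bracketing standards it sees.
#'
#' @param config [mass_config()].
#' @param seed root seed (drift slopes are drawn per run).
#' @return list with named numeric vectors `blank_mean`, `sensitivity`,
#'   `drift_slope` and scalars `acquisition_rate` (points/s), `scan_speed`
#'   (um/s), `spot_um`, `srba_scale` (ppm Sr at unit Sr:Ba index).
#' @export
instrument_model <- function(config = mass_config(), seed = 1L) {
  lab <- config$isotopes$label
  blank_defaults <- c(Li7 = 25, Mg24 = 60, Ca43 = 500, Mn55 = 30, Fe57 = 80,
                      Co59 = 15, Cu63 = 40, Rb85 = 20, Sr88 = 50, Y89 = 12,
                      Ba137 = 30, Pb208 = 25, U238 = 10)
  sens_defaults <- c(Li7 = 700, Mg24 = 650, Ca43 = 50, Mn55 = 600, Fe57 = 550,
                     Co59 = 620, Cu63 = 580, Rb85 = 640, Sr88 = 600, Y89 = 660,
                     Ba137 = 500, Pb208 = 560, U238 = 700)
  blank <- ifelse(lab %in% names(blank_defaults), blank_defaults[lab], 30)
  sens <- ifelse(lab %in% names(sens_defaults), sens_defaults[lab], 600)
  names(blank) <- names(sens) <- lab
  drift <- with_substream(seed, "drift_slopes",
                          stats::setNames(runif(length(lab), -0.05, 0.08), lab))
  list(blank_mean = blank, sensitivity = sens, drift_slope = drift,
       acquisition_rate = 5, scan_speed = 10, spot_um = 83,
       srba_scale = 20)
}

#' Linear per-mass drift factor at an acquisition order
#' @keywords internal
drift_factor <- function(instrument, order, n_orders) {
  if (n_orders <= 1) return(rep(1, length(instrument$drift_slope)))
  1 + instrument$drift_slope * (order - 1) / (n_orders - 1)
}

#' Render one ablation record from ground truth
#'
#' Forward model of the instrument: cps(t, mass) = blank baseline +
#' sensitivity x drift(order) x true ppm(t), with Poisson-like counting noise
#' (Gaussian, SD = sqrt(mean)) plus 2\% multiplicative flicker, both scaled
#' by `noise`, and rare single-point spikes (each point multiplied by
#' Uniform(5, 20) with probability `spike_prob`). Gas blanks carry the
#' baseline only. Spot records hold a 60 s signal plateau, transects a signal
#' of duration scan length / scan speed; both are framed by short baseline
#' segments before laser-on and after laser-off.
#'
#' @param role one of `"gas_blank"`, `"nist612"`, `"macs3"`, `"spot"`,
#'   `"transect"`.
#' @param true_ppm named vector of true concentrations (standards/spots), or
#'   a points x masses matrix for transects; ignored for gas blanks.
#' @param config [mass_config()].
#' @param instrument [instrument_model()].
#' @param order acquisition order of this record.
#' @param n_orders total records in the run (drift normalization).
#' @param noise noise scale (0 = deterministic forward model).
#' @param spike_prob per-point spike probability.
#' @param seed root seed; the record draws from the substream named by
#'   `record_id`.
#' @param record_id unique record identifier.
#' @param specimen_id,target,replicate,slide,std_bracket manifest metadata.
#' @param scan_length_um transect scan length (transects only).
#' @param scan_origin `"focus"` if the scan started at the focus end.
#' @return object of class `ablation_record`.
#' @export
render_ablation <- function(role, true_ppm = NULL, config = mass_config(),
                            instrument = instrument_model(config),
                            order = 1L, n_orders = 1L,
                            noise = 1, spike_prob = 0.01,
                            seed = 1L, record_id = "r1",
                            specimen_id = NA_character_,
                            target = NA_character_, replicate = NA_integer_,
                            slide = NA_integer_, std_bracket = NA_integer_,
                            scan_length_um = NA_real_,
                            scan_origin = "focus") {
  roles <- c("gas_blank", "nist612", "macs3", "spot", "transect")
  if (!role %in% roles) stop("unknown role '", role, "'")
  lab <- config$isotopes$label
  rate <- instrument$acquisition_rate
  head_s <- 5
  dur <- switch(role,
                gas_blank = 60,
                spot = ,
                nist612 = ,
                macs3 = 60,
                transect = scan_length_um / instrument$scan_speed)
  if (role == "transect" && (!is.finite(dur) || dur <= 0)) {
    stop("transect records need a positive scan_length_um")
  }
  n_sig <- max(1L, round(dur * rate))
  if (role == "gas_blank") {
    n_head <- 0L
    n_tail <- 0L
  } else {
    n_head <- round(head_s * rate)
    n_tail <- round(head_s * rate)
  }
  n <- n_head + n_sig + n_tail
  time_s <- (seq_len(n) - 1) / rate

  d <- drift_factor(instrument, order, n_orders)
  mu <- matrix(rep(instrument$blank_mean, each = n), nrow = n,
               dimnames = list(NULL, lab))
  if (role != "gas_blank") {
    sig_rows <- n_head + seq_len(n_sig)
    if (is.matrix(true_ppm)) {
      if (nrow(true_ppm) != n_sig) {
        stop("true_ppm matrix must have one row per signal point (", n_sig, ")")
      }
      ppm_mat <- true_ppm[, lab, drop = FALSE]
    } else {
      ppm <- rep(0, length(lab))
      names(ppm) <- lab
      ppm[names(true_ppm)] <- true_ppm
      ppm_mat <- matrix(rep(ppm, each = n_sig), nrow = n_sig,
                        dimnames = list(NULL, lab))
    }
    add <- sweep(ppm_mat, 2, instrument$sensitivity[lab] * d, `*`)
    mu[sig_rows, ] <- mu[sig_rows, ] + add
  }
  cps <- with_substream(seed, record_id, {
    x <- mu
    if (noise > 0) {
      sd_mat <- noise * (sqrt(pmax(mu, 1)) + 0.02 * mu)
      x <- mu + matrix(rnorm(length(mu)), nrow = n) * sd_mat
      x <- pmax(x, 0)
    }
    if (spike_prob > 0 && role != "gas_blank") {
      hit <- matrix(runif(length(x)) < spike_prob, nrow = n)
      if (any(hit)) x[hit] <- x[hit] * runif(sum(hit), 5, 20)
    }
    x
  })
  structure(list(record_id = record_id, role = role,
                 specimen_id = specimen_id, target = target,
                 replicate = replicate, order = as.integer(order),
                 slide = slide, std_bracket = std_bracket,
                 time_s = time_s, cps = cps,
                 spot_um = if (role %in% c("spot", "nist612", "macs3"))
                   instrument$spot_um else NA_real_,
                 scan_speed_um_s = if (role == "transect")
                   instrument$scan_speed else NA_real_,
                 scan_length_um = if (role == "transect")
                   scan_length_um else NA_real_,
                 scan_origin = if (role == "transect") scan_origin
                 else NA_character_,
                 signal_window_s = if (role == "gas_blank") c(NA_real_, NA_real_)
                 else time_s[c(n_head + 1L, n_head + n_sig)]),
            class = "ablation_record")
}

#' Map a migration trajectory onto per-point true concentrations
#'
#' Interpolates the trajectory onto the transect grid and overwrites the
#' Sr, Ba, Pb and internal-standard columns of a base ppm matrix so that,
#' under the instrument's sensitivities, the raw cps ratios reproduce the
#' trajectory: Sr and Ba split the Sr:Ba index as sqrt(r) and 1/sqrt(r)
#' (which also makes Sr:Ca rise while Ba:Ca falls, their observed inverse
#' relation), and Pb tracks the Pb:Ca index.
#'
#' @keywords internal
traj_ppm_matrix <- function(tr, base, instrument, config) {
  n_pts <- nrow(base)
  fgrid <- seq(0, 1, length.out = n_pts)
  tgrid <- seq(0, 1, length.out = tr$n_points)
  srba <- stats::approx(tgrid, tr$srba_env, fgrid)$y
  pb <- stats::approx(tgrid, tr$pb_env, fgrid)$y
  sr_scale <- instrument$srba_scale
  ba_scale <- instrument$sensitivity[["Sr88"]] * sr_scale /
    instrument$sensitivity[["Ba137"]]
  pb_scale <- 1e-6 * instrument$sensitivity[[config$internal_standard]] *
    ca_ppm(config) / instrument$sensitivity[["Pb208"]]
  m <- base
  m[, config$internal_standard] <- ca_ppm(config)
  m[, "Sr88"] <- sr_scale * sqrt(srba)
  m[, "Ba137"] <- ba_scale / sqrt(srba)
  m[, "Pb208"] <- pb_scale * pb
  m
}

#' Simulate and reduce one stand-alone YOY transect
#'
#' Convenience wrapper for studying the profile classifier in isolation:
#' draws a gestation trajectory, renders it as a transect ablation inside a
#' minimal run (gas blanks and two NIST-612 calibration pairs), builds the
#' calibration model and reduces the transect.
#'
#' @param pattern 1 or 2.
#' @param l_birth_cm length at birth (cm) setting the focus-to-birthmark
#'   scan length via the length-radius relation.
#' @param noise,spike_prob instrument corruption settings.
#' @param env_noise environmental jitter (Sr:Ba index units).
#' @param seed seed for this transect's trajectory and rendering.
#' @param config [mass_config()]; needs Sr88, Ba137, Pb208 and the internal
#'   standard.
#' @return list with `profile` (`transect_profile`), `trajectory`
#'   (`migration_trajectory`) and `run`.
#' @export
simulate_transect <- function(pattern, l_birth_cm = 48, noise = 1,
                              spike_prob = 0.01, env_noise = 15, seed = 1L,
                              config = mass_config()) {
  instrument <- instrument_model(config, seed)
  scan_um <- radius_from_length(l_birth_cm) * 1000
  n_pts <- max(50L, round(scan_um / instrument$scan_speed *
                            instrument$acquisition_rate))
  tr <- simulate_trajectory(pattern, max(50L, n_pts), env_noise = env_noise,
                            seed = seed)
  lab <- config$isotopes$label
  base <- matrix(rep(ratio_to_ppm(base_ratios(lab), config), each = n_pts),
                 nrow = n_pts, dimnames = list(NULL, lab))
  ppm <- traj_ppm_matrix(tr, base, instrument, config)
  iso <- config$isotopes
  nist_ppm <- stats::setNames(iso$nist612_ppm, iso$label)
  n_orders <- 11L
  recs <- list()
  oi <- 0L
  emit <- function(role, ...) {
    oi <<- oi + 1L
    recs[[oi]] <<- render_ablation(role, ..., config = config,
                                   instrument = instrument, order = oi,
                                   n_orders = n_orders, seed = seed)
  }
  emit("gas_blank", noise = noise, spike_prob = 0, record_id = "B1")
  emit("nist612", nist_ppm, noise = noise, spike_prob = spike_prob,
       record_id = "N1_1", std_bracket = 1L)
  emit("gas_blank", noise = noise, spike_prob = 0, record_id = "B2")
  emit("nist612", nist_ppm, noise = noise, spike_prob = spike_prob,
       record_id = "N1_2", std_bracket = 1L)
  emit("gas_blank", noise = noise, spike_prob = 0, record_id = "B3")
  emit("transect", ppm, noise = noise, spike_prob = spike_prob,
       record_id = "T1", specimen_id = "YOY", target = "transect",
       scan_length_um = scan_um, scan_origin = "focus")
  emit("gas_blank", noise = noise, spike_prob = 0, record_id = "B4")
  emit("nist612", nist_ppm, noise = noise, spike_prob = spike_prob,
       record_id = "N2_1", std_bracket = 2L)
  emit("gas_blank", noise = noise, spike_prob = 0, record_id = "B5")
  emit("nist612", nist_ppm, noise = noise, spike_prob = spike_prob,
       record_id = "N2_2", std_bracket = 2L)
  emit("gas_blank", noise = noise, spike_prob = 0, record_id = "B6")
  run <- run_sequence(recs, config, root_seed = seed)
  model <- build_drift_model(run, config)
  profile <- reduce_transect(run$records[["T1"]], run, model)
  list(profile = profile, trajectory = tr, run = run)
}

# element:Ca base ratios (umol/mol) around which litter signatures are drawn
base_ratios <- function(lab) {
  base <- c(Li7 = 15, Mg24 = 10000, Ca43 = 1e6, Mn55 = 20, Fe57 = 500,
            Co59 = 1, Cu63 = 5, Rb85 = 2, Sr88 = 2000, Y89 = 0.3,
            Ba137 = 10, Pb208 = 1, U238 = 0.05)
  out <- ifelse(lab %in% names(base), base[lab], 1)
  names(out) <- lab
  out
}

#' element:Ca ratio (umol/mol) -> ppm under the assumed Ca mass fraction
#' @keywords internal
ratio_to_ppm <- function(ratio_umol_mol, config) {
  iso <- config$isotopes
  a <- stats::setNames(iso$atomic_mass, iso$label)
  a_ca <- a[[config$internal_standard]]
  ratio_umol_mol * 1e-6 * (ca_ppm(config) / a_ca) * a[names(ratio_umol_mol)]
}

#' ppm -> element:Ca ratio (umol/mol) under the assumed Ca mass fraction
#' @keywords internal
ppm_to_ratio <- function(ppm, config) {
  iso <- config$isotopes
  a <- stats::setNames(iso$atomic_mass, iso$label)
  a_ca <- a[[config$internal_standard]]
  (ppm / a[names(ppm)]) / (ca_ppm(config) / a_ca) * 1e6
}

#' Generate a complete synthetic LA-ICP-MS study
#'
#' Builds the full experiment the pipeline consumes: a specimen table
#' (females, embryos, YOY with lengths, radii and grouping), ground-truth
#' litter signatures and per-mother migration trajectories, and a rendered
#' run sequence in acquisition order with gas blanks before every ablation
#' (and after the last), NIST-612 calibration pairs before the first and
#' after every fifth vertebral section, MACS-3 brackets around every slide,
#' three-replicate focus and edge spots per embryo, edge spots per female,
#' and focus-to-edge (embryo) / focus-to-birthmark (YOY) transects.
#'
#' A mother's edge-period environment vector is identical to her embryos'
#' (the maternal tag is built in), and her embryos' transects follow her
#' single gestation trajectory.
#'
#' @param design [study_design()].
#' @param config [mass_config()]; must include the internal standard.
#' @param noise noise scale passed to [render_ablation()].
#' @param spike_prob per-point spike probability.
#' @param litter_sd_log between-litter log-SD of element:Ca signatures
#'   (default 0.15, i.e. maternal tags differing by tens of percent).
#' @param replicate_sd_log within-spot between-replicate log-SD of element
#'   concentrations (default 0.05): replicate ablations sample slightly
#'   different material, the heterogeneity that replicate screening exists
#'   to police. Set to 0 (with `noise = 0`, `spike_prob = 0`) for a fully
#'   deterministic forward model.
#' @param env_noise environmental jitter passed to [simulate_trajectory()].
#' @return list with components `run` (class `run_sequence`), `specimens`
#'   (data.frame) and `truth` (class `synthetic_truth`).
#' @export
#' @examples
#' st <- make_study(study_design(n_females = 2, litter_sizes = c(2, 2),
#'                               n_yoy = 2, seed = 7))
#' nrow(st$specimens)
make_study <- function(design = study_design(), config = mass_config(),
                       noise = 1, spike_prob = 0.01,
                       litter_sd_log = 0.15, replicate_sd_log = 0.05,
                       env_noise = 15) {
  stopifnot(inherits(design, "study_design"), inherits(config, "mass_config"))
  lab <- config$isotopes$label
  is_lab <- config$internal_standard
  seed <- design$seed
  instrument <- instrument_model(config, seed)
  bc <- backcalc_params()

  ## ---- specimens -------------------------------------------------------
  nF <- design$n_females
  nE <- sum(design$litter_sizes)
  nY <- design$n_yoy
  female_l <- if (!is.null(design$female_lengths)) {
    as.numeric(design$female_lengths)
  } else {
    with_substream(seed, "female_lengths",
                   sort(runif(nF, design$female_length_range[1],
                              design$female_length_range[2]), decreasing = TRUE))
  }
  embryo_l <- with_substream(seed, "embryo_lengths",
                             runif(nE, design$embryo_length_range[1],
                                   design$embryo_length_range[2]))
  yoy_l <- with_substream(seed, "yoy_lengths",
                          runif(nY, design$yoy_length_range[1],
                                design$yoy_length_range[2]))
  yoy_birth_l <- with_substream(seed, "yoy_birth_lengths",
                                runif(nY, design$birth_length_range[1],
                                      design$birth_length_range[2]))
  # a YOY's birth length cannot exceed its capture length
  yoy_birth_l <- pmin(yoy_birth_l, yoy_l - 0.5)

  female_id <- sprintf("F%02d", seq_len(nF))
  embryo_id <- sprintf("E%02d", seq_len(nE))
  yoy_id <- sprintf("Y%02d", seq_len(nY))
  embryo_litter <- rep(seq_len(nF), design$litter_sizes)
  yoy_site <- if (nY > 0) {
    paste0("site", sort(rep_len(seq_len(design$n_sites), nY)))
  } else character(0)

  specimens <- data.frame(
    specimen_id = c(female_id, embryo_id, yoy_id),
    class = c(rep("female", nF), rep("embryo", nE), rep("yoy", nY)),
    group = c(paste0("litter", seq_len(nF)),
              paste0("litter", embryo_litter), yoy_site),
    l_c_cm = c(female_l, embryo_l, yoy_l),
    stringsAsFactors = FALSE
  )
  # adult females are far outside the juvenile length-radius relation; give
  # them a nominal large radius (only embryo/YOY radii are used downstream)
  specimens$r_v_mm <- ifelse(specimens$class == "female",
                             specimens$l_c_cm / 17.349,
                             radius_from_length(specimens$l_c_cm, bc))
  specimens$l_birth_cm <- NA_real_
  if (nY > 0) specimens$l_birth_cm[specimens$class == "yoy"] <- yoy_birth_l

  ## ---- ground-truth signatures and trajectories ------------------------
  bases <- base_ratios(lab)
  sig_list <- list()
  for (l in seq_len(nF)) {
    for (tg in c("focus", "edge")) {
      ratios <- with_substream(seed, paste0("litter_sig_", l, "_", tg), {
        r <- bases * exp(rnorm(length(bases), 0, litter_sd_log))
        r[is_lab] <- 1e6
        r
      })
      sig_list[[paste0("litter", l, "_", tg)]] <- ratios
    }
  }
  yoy_sig <- list()
  for (i in seq_len(nY)) {
    for (tg in c("focus", "edge")) {
      ratios <- with_substream(seed, paste0("yoy_sig_", i, "_", tg), {
        r <- bases * exp(rnorm(length(bases), 0, litter_sd_log))
        r[is_lab] <- 1e6
        r
      })
      yoy_sig[[paste0(yoy_id[i], "_", tg)]] <- ratios
    }
  }

  traj_res <- 600L
  mother_traj <- lapply(seq_len(nF), function(l) {
    simulate_trajectory(1, traj_res, env_noise = env_noise,
                        seed = substream_seed(seed, paste0("mother_traj_", l)))
  })
  n_p1 <- if (nY > 0) as.integer(round(design$pattern_mix * nY)) else 0L
  yoy_pattern <- if (nY > 0) {
    with_substream(seed, "yoy_patterns",
                   sample(c(rep(1L, n_p1), rep(2L, nY - n_p1))))
  } else integer(0)
  yoy_traj <- lapply(seq_len(nY), function(i) {
    simulate_trajectory(yoy_pattern[i], traj_res, env_noise = env_noise,
                        seed = substream_seed(seed, paste0("yoy_traj_", i)))
  })

  ## ---- run sequence assembly ------------------------------------------
  # section order: females, embryos, yoy; slides of up to 11 sections
  section_ids <- specimens$specimen_id
  n_sections <- length(section_ids)
  slide_of <- ceiling(seq_len(n_sections) / 11)

  plan <- list()  # ablation plan entries (role + metadata), blanks added later
  std_bracket <- 0L
  add <- function(entry) plan[[length(plan) + 1L]] <<- entry
  nist_pair <- function() {
    std_bracket <<- std_bracket + 1L
    for (r in 1:2) {
      add(list(role = "nist612", replicate = r, std_bracket = std_bracket))
    }
  }
  macs_one <- function(slide) add(list(role = "macs3", slide = slide))

  cur_slide <- 0L
  for (s in seq_len(n_sections)) {
    if (slide_of[s] != cur_slide) {
      if (cur_slide > 0L) macs_one(cur_slide)     # close previous slide
      cur_slide <- slide_of[s]
      macs_one(cur_slide)                         # open new slide
    }
    if (s %% 5L == 1L) nist_pair()                # before section 1, 6, 11, ...
    sp <- specimens[s, ]
    if (sp$class == "female") {
      for (r in 1:3) add(list(role = "spot", specimen = sp$specimen_id,
                              target = "edge", replicate = r,
                              slide = cur_slide))
    } else if (sp$class == "embryo") {
      for (tg in c("focus", "edge")) {
        for (r in 1:3) add(list(role = "spot", specimen = sp$specimen_id,
                                target = tg, replicate = r, slide = cur_slide))
      }
      add(list(role = "transect", specimen = sp$specimen_id,
               target = "transect", slide = cur_slide,
               scan_length_um = sp$r_v_mm * 1000))
    } else {
      add(list(role = "transect", specimen = sp$specimen_id,
               target = "transect", slide = cur_slide,
               scan_length_um = radius_from_length(sp$l_birth_cm, bc) * 1000))
    }
  }
  if (n_sections > 0L) {
    nist_pair()                                   # trailing calibration pair
    macs_one(cur_slide)                           # close last slide
  }

  # interleave gas blanks: one before every ablation, one after the last
  n_abl <- length(plan)
  n_orders <- 2L * n_abl + 1L
  records <- vector("list", n_orders)
  truth_records <- list()
  iso <- config$isotopes
  nist_ppm <- stats::setNames(iso$nist612_ppm, iso$label)
  macs_ppm <- stats::setNames(iso$macs3_ppm, iso$label)
  sr_scale <- instrument$srba_scale
  ba_scale <- instrument$sensitivity[["Sr88"]] * sr_scale /
    instrument$sensitivity[["Ba137"]]
  pb_scale <- 1e-6 * instrument$sensitivity[[is_lab]] * ca_ppm(config) /
    instrument$sensitivity[["Pb208"]]

  transect_ppm <- function(spec_id, n_pts) {
    sp <- specimens[specimens$specimen_id == spec_id, ]
    if (sp$class == "embryo") {
      l <- embryo_litter[match(spec_id, embryo_id)]
      tr <- mother_traj[[l]]
      sig_f <- sig_list[[paste0("litter", l, "_focus")]]
      sig_e <- sig_list[[paste0("litter", l, "_edge")]]
    } else {
      i <- match(spec_id, yoy_id)
      tr <- yoy_traj[[i]]
      sig_f <- yoy_sig[[paste0(spec_id, "_focus")]]
      sig_e <- yoy_sig[[paste0(spec_id, "_edge")]]
    }
    fgrid <- seq(0, 1, length.out = n_pts)
    ppm_f <- ratio_to_ppm(sig_f, config)
    ppm_e <- ratio_to_ppm(sig_e, config)
    base <- sapply(lab, function(el) {
      ppm_f[[el]] + (ppm_e[[el]] - ppm_f[[el]]) * fgrid
    })
    traj_ppm_matrix(tr, base, instrument, config)
  }

  order_i <- 0L
  blank_i <- 0L
  emit <- function(rec) {
    records[[rec$order]] <<- rec
  }
  next_blank <- function() {
    order_i <<- order_i + 1L
    blank_i <<- blank_i + 1L
    emit(render_ablation("gas_blank", config = config, instrument = instrument,
                         order = order_i, n_orders = n_orders, noise = noise,
                         spike_prob = 0, seed = seed,
                         record_id = sprintf("B%03d", blank_i)))
  }
  spot_i <- 0L
  for (k in seq_len(n_abl)) {
    next_blank()
    p <- plan[[k]]
    order_i <- order_i + 1L
    rid <- switch(p$role,
                  nist612 = sprintf("N%02d_%d", p$std_bracket, p$replicate),
                  macs3 = sprintf("M%02d", k),
                  spot = sprintf("S_%s_%s_%d", p$specimen, p$target,
                                 p$replicate),
                  transect = sprintf("T_%s", p$specimen))
    if (p$role == "nist612") {
      rec <- render_ablation("nist612", nist_ppm, config, instrument,
                             order_i, n_orders, noise, spike_prob, seed, rid,
                             std_bracket = p$std_bracket)
      true_ppm <- nist_ppm
    } else if (p$role == "macs3") {
      rec <- render_ablation("macs3", macs_ppm, config, instrument,
                             order_i, n_orders, noise, spike_prob, seed, rid,
                             slide = p$slide)
      true_ppm <- macs_ppm
    } else if (p$role == "spot") {
      sp <- specimens[specimens$specimen_id == p$specimen, ]
      sig <- if (sp$class == "female" || sp$class == "embryo") {
        l <- if (sp$class == "female") match(p$specimen, female_id) else
          embryo_litter[match(p$specimen, embryo_id)]
        sig_list[[paste0("litter", l, "_", p$target)]]
      } else {
        yoy_sig[[paste0(p$specimen, "_", p$target)]]
      }
      true_ppm <- ratio_to_ppm(sig, config)
      true_ppm[is_lab] <- ca_ppm(config)
      if (replicate_sd_log > 0) {
        jit <- with_substream(seed, paste0("rep_jitter_", rid),
                              exp(rnorm(length(true_ppm), 0,
                                        replicate_sd_log)))
        names(jit) <- names(true_ppm)
        jit[is_lab] <- 1
        true_ppm <- true_ppm * jit
      }
      rec <- render_ablation("spot", true_ppm, config, instrument,
                             order_i, n_orders, noise, spike_prob, seed, rid,
                             specimen_id = p$specimen, target = p$target,
                             replicate = p$replicate, slide = p$slide)
      spot_i <- spot_i + 1L
    } else {
      n_pts <- max(1L, round(p$scan_length_um / instrument$scan_speed *
                               instrument$acquisition_rate))
      true_ppm <- transect_ppm(p$specimen, n_pts)
      rec <- render_ablation("transect", true_ppm, config, instrument,
                             order_i, n_orders, noise, spike_prob, seed, rid,
                             specimen_id = p$specimen, target = "transect",
                             slide = p$slide,
                             scan_length_um = p$scan_length_um,
                             scan_origin = "focus")
    }
    truth_records[[rid]] <- list(true_ppm = true_ppm, order = order_i,
                                 drift = drift_factor(instrument, order_i,
                                                      n_orders))
    emit(rec)
  }
  if (n_abl > 0L) next_blank()
  records <- records[seq_len(order_i)]

  run <- run_sequence(records, config, root_seed = seed)

  truth <- structure(list(
    specimens = specimens,
    litter_signatures = sig_list,
    yoy_signatures = yoy_sig,
    mother_trajectories = mother_traj,
    yoy_trajectories = yoy_traj,
    yoy_pattern = if (nY > 0) stats::setNames(yoy_pattern, yoy_id) else
      integer(0),
    yoy_shift_fraction = if (nY > 0) {
      stats::setNames(vapply(yoy_traj, function(t) t$shift_fraction,
                             numeric(1)), yoy_id)
    } else numeric(0),
    records = truth_records,
    instrument = instrument,
    noise = noise, spike_prob = spike_prob
  ), class = "synthetic_truth")

  list(run = run, specimens = specimens, truth = truth)
}

#' Assemble a run sequence from ablation records
#'
#' @param records list of `ablation_record` objects in acquisition order.
#' @param config [mass_config()].
#' @param root_seed seed recorded for provenance.
#' @return object of class `run_sequence` with a `manifest` data.frame.
#' @export
run_sequence <- function(records, config, root_seed = NA_integer_) {
  stopifnot(length(records) > 0)
  ids <- vapply(records, function(r) r$record_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate record ids in run")
  manifest <- do.call(rbind, lapply(records, function(r) {
    data.frame(record_id = r$record_id, role = r$role,
               specimen_id = r$specimen_id, target = r$target,
               replicate = r$replicate, order = r$order, slide = r$slide,
               std_bracket = r$std_bracket, spot_um = r$spot_um,
               scan_speed_um_s = r$scan_speed_um_s,
               scan_length_um = r$scan_length_um,
               scan_origin = r$scan_origin, stringsAsFactors = FALSE)
  }))
  names(records) <- ids
  structure(list(records = records, manifest = manifest, config = config,
                 root_seed = root_seed),
            class = "run_sequence")
}

#' @export
print.run_sequence <- function(x, ...) {
  tab <- table(x$manifest$role)
  cat("LA-ICP-MS run sequence:", nrow(x$manifest), "records\n  ")
  cat(paste(names(tab), as.integer(tab), sep = ": ", collapse = " | "), "\n")
  invisible(x)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth:", nrow(x$specimens), "specimens |",
      length(x$records), "ablations\n")
  if (length(x$yoy_pattern)) {
    cat("  YOY patterns:", sum(x$yoy_pattern == 1), "Pattern 1,",
        sum(x$yoy_pattern == 2), "Pattern 2\n")
  }
  invisible(x)
}
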