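#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its standard
#' default: the study design and mass configuration, the signal-reduction
#' thresholds (Grubbs alpha 0.05, LOD multiplier 3 via the calibration
#' model, below-LOD fraction 0.10, outlyingness cutoff 10), the profile
#' settings (11-point smoothing window, pattern thresholds), permutation
#' counts, back-calculation parameters, and output location.
#'
#' @param design [study_design()].
#' @param config [mass_config()].
#' @param out_dir artifact directory (`NULL` = no files written).
#' @param input_dir optional directory with an existing run
#'   (`manifest.csv` + `records/`); used when the simulate stage is
#'   skipped.
#' @param noise,spike_prob generator settings.
#' @param grubbs_alpha,lod_threshold,outlyingness_cutoff reduction
#'   thresholds.
#' @param smoothing_window,thresholds profile settings.
#' @param n_perm,seed permutation settings (seed defaults to the design
#'   seed).
#' @param backcalc [backcalc_params()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = study_design(), config = mass_config(),
                            out_dir = NULL, input_dir = NULL,
                            noise = 1, spike_prob = 0.01,
                            grubbs_alpha = 0.05, lod_threshold = 0.10,
                            outlyingness_cutoff = 10,
                            smoothing_window = 11,
                            thresholds = pattern_thresholds(),
                            n_perm = 999, seed = design$seed,
                            backcalc = backcalc_params()) {
  structure(list(design = design, config = config, out_dir = out_dir,
                 input_dir = input_dir, noise = noise,
                 spike_prob = spike_prob, grubbs_alpha = grubbs_alpha,
                 lod_threshold = lod_threshold,
                 outlyingness_cutoff = outlyingness_cutoff,
                 smoothing_window = smoothing_window,
                 thresholds = thresholds, n_perm = n_perm, seed = seed,
                 backcalc = backcalc),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "out_dir")]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_artifact <- function(df, cfg, name, log) {
  if (is.null(cfg$out_dir)) return(invisible(NULL))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(cfg$out_dir, name)
  header <- sprintf("# sharktrace %s | config %s | seed %s",
                    as.character(utils::packageVersion("sharktrace")),
                    config_hash(cfg), cfg$seed)
  writeLines(header, path)
  suppressWarnings(utils::write.table(df, path, append = TRUE, sep = ",",
                                      row.names = FALSE, qmethod = "double"))
  log(paste("wrote", name))
}

#' Run the end-to-end analysis
#'
#' Executes the selected stages in order:
#' \describe{
#'   \item{simulate}{generate the synthetic study ([make_study()]); skipped
#'     stages require `input_dir` with an existing run.}
#'   \item{reduce}{calibration model, spot signatures with replicate
#'     screening and the below-LOD element filter, transect profiles.}
#'   \item{stats}{the three maternal-tag hypotheses: (H1) embryo focus and
#'     edge signatures by litter, (H2) embryo transect profiles by litter,
#'     (H3) edge signatures of each female together with her embryos —
#'     each via PERMANOVA, CAP with LOO cross-validation, and PCC.}
#'   \item{profiles}{Sr:Ba / Pb:Ca ratio profiles and migration-pattern
#'     calls for YOY and embryo transects, with the focus-segment Pb:Ca
#'     rank-sum comparison between patterns.}
#'   \item{backcalc}{Fraser-Lee back-calculated length at the habitat
#'     shift for every Pattern-1 call.}
#' }
#' Every threshold, seed and exclusion decision is appended to
#' `pipeline.log` in `out_dir` (when set), and artifacts carry a header
#' with package version, configuration hash and root seed.
#'
#' @param cfg [pipeline_config()].
#' @param stages character subset of
#'   `c("simulate", "reduce", "stats", "profiles", "backcalc")`.
#' @return list of stage results, invisibly: `study`, `model`, `spots`,
#'   `profiles_embryo`, `profiles_yoy`, `stats`, `calls`, `backcalc`.
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         stages = c("simulate", "reduce", "stats",
                                    "profiles", "backcalc")) {
  all_stages <- c("simulate", "reduce", "stats", "profiles", "backcalc")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
  }
  needs <- function(stage, dep, have) {
    if (stage %in% stages && !dep %in% stages && !have) {
      stop("stage '", stage, "' requires '", dep,
           "' (or pre-existing inputs)")
    }
  }
  needs("reduce", "simulate", !is.null(cfg$input_dir))
  for (s in c("stats", "profiles")) needs(s, "reduce", FALSE)
  needs("backcalc", "profiles", FALSE)

  res <- list()
  log(sprintf("thresholds: grubbs_alpha=%g lod_fraction=%g outlyingness=%g window=%d t_low=%g t_peak=%g t_return=%g seed=%s",
              cfg$grubbs_alpha, cfg$lod_threshold, cfg$outlyingness_cutoff,
              cfg$smoothing_window, cfg$thresholds$t_low,
              cfg$thresholds$t_peak, cfg$thresholds$t_return, cfg$seed))

  ## simulate -------------------------------------------------------------
  if ("simulate" %in% stages) {
    res$study <- make_study(cfg$design, cfg$config, noise = cfg$noise,
                            spike_prob = cfg$spike_prob)
    log(sprintf("simulated %d records, %d specimens",
                nrow(res$study$run$manifest), nrow(res$study$specimens)))
    if (!is.null(cfg$out_dir)) {
      write_run(res$study$run, file.path(cfg$out_dir, "run"),
                res$study$specimens, res$study$truth)
      log("wrote run/ (records, manifest, specimens, truth)")
    }
  } else if (!is.null(cfg$input_dir)) {
    run <- read_run(file.path(cfg$input_dir, "manifest.csv"),
                    config = cfg$config)
    spec_path <- file.path(cfg$input_dir, "specimens.csv")
    specimens <- if (file.exists(spec_path)) {
      utils::read.csv(spec_path, stringsAsFactors = FALSE)
    } else NULL
    res$study <- list(run = run, specimens = specimens, truth = NULL)
    log(sprintf("loaded run from %s (%d records)", cfg$input_dir,
                nrow(run$manifest)))
  }
  run <- res$study$run
  specimens <- res$study$specimens

  ## reduce ---------------------------------------------------------------
  if ("reduce" %in% stages) {
    res$model <- build_drift_model(run, cfg$config, alpha = cfg$grubbs_alpha)
    if (length(res$model$uncalibratable)) {
      log(paste("uncalibratable masses:",
                paste(res$model$uncalibratable, collapse = ", ")))
    }
    res$spots <- reduce_spots(run, res$model,
                              cutoff = cfg$outlyingness_cutoff,
                              lod_threshold = cfg$lod_threshold,
                              seed = cfg$seed)
    for (id in res$spots$excluded_replicates) {
      log(sprintf("replicate %s excluded: outlyingness %.1f > %g", id,
                  res$spots$outlyingness[[id]], cfg$outlyingness_cutoff))
    }
    if (nrow(res$spots$dropped)) {
      for (i in seq_len(nrow(res$spots$dropped))) {
        log(sprintf("element %s dropped: %.1f%% of measures below LOD (>= %g%%)",
                    res$spots$dropped$element[i],
                    100 * res$spots$dropped$below_lod_fraction[i],
                    100 * cfg$lod_threshold))
      }
    }
    man <- run$manifest
    tr_ids <- man$record_id[man$role == "transect"]
    profs <- lapply(tr_ids, function(id) {
      reduce_transect(run$records[[id]], run, res$model)
    })
    names(profs) <- vapply(profs, function(p) p$specimen_id, character(1))
    cls <- specimens$class[match(names(profs), specimens$specimen_id)]
    res$profiles_embryo <- profs[!is.na(cls) & cls == "embryo"]
    res$profiles_yoy <- profs[!is.na(cls) & cls == "yoy"]
    log(sprintf("reduced %d spots -> %d retained elements; %d transects",
                length(unique(paste(man$specimen_id, man$target)[man$role == "spot"])),
                length(res$spots$retained), length(profs)))
    write_artifact(res$spots$signatures, cfg, "signatures.csv", log)
  }

  ## stats ----------------------------------------------------------------
  if ("stats" %in% stages) {
    sig <- res$spots$signatures
    retained <- setdiff(res$spots$retained, cfg$config$internal_standard)
    feature_matrix <- function(class_keep, target_keep) {
      keep <- specimens$class[match(sig$specimen_id,
                                    specimens$specimen_id)] %in% class_keep &
        sig$target == target_keep & sig$element %in% retained
      s <- sig[keep, , drop = FALSE]
      stats::xtabs(ratio_umol_mol ~ specimen_id + element, data = s)
    }
    groups_of <- function(x) {
      factor(specimens$group[match(rownames(x), specimens$specimen_id)])
    }
    run_test <- function(x, label) {
      g <- groups_of(x)
      pm <- permanova(euclidean_dm(unclass(x)), g, n_perm = cfg$n_perm,
                      seed = cfg$seed)
      cap <- cap_fit(euclidean_dm(unclass(x)), g, m = "auto",
                     n_perm = cfg$n_perm, seed = cfg$seed)
      log(sprintf("%s: pseudo-F=%.3g P=%.3g | CAP m=%d LOO %.1f%% vs chance %.1f%%",
                  label, pm$pseudo_f, pm$p_value, cap$m, cap$loo_accuracy,
                  cap$pcc$chance_accuracy))
      list(permanova = pm, cap = cap)
    }
    res$stats <- list(
      h1_focus = run_test(feature_matrix("embryo", "focus"), "H1 focus"),
      h1_edge = run_test(feature_matrix("embryo", "edge"), "H1 edge"),
      h3_edge = run_test(feature_matrix(c("embryo", "female"), "edge"),
                         "H3 edge")
    )
    if (length(res$profiles_embryo) >= 2) {
      rs <- resample_transects(res$profiles_embryo, elements = retained,
                               value = "ppm")
      res$stats$h2_transect <- run_test(rs$features, "H2 transect")
    }
    rep_rows <- do.call(rbind, lapply(names(res$stats), function(nm) {
      st <- res$stats[[nm]]
      data.frame(hypothesis = nm, pseudo_f = st$permanova$pseudo_f,
                 permanova_p = st$permanova$p_value, cap_m = st$cap$m,
                 g_prop = st$cap$g_prop, trc_stat = st$cap$trc_stat,
                 cap_p = st$cap$p_value, loo_accuracy = st$cap$loo_accuracy,
                 chance_accuracy = st$cap$pcc$chance_accuracy,
                 pcc_p = st$cap$pcc$p_value, stringsAsFactors = FALSE)
    }))
    write_artifact(rep_rows, cfg, "stats_report.csv", log)
    res$stats_report <- rep_rows
  }

  ## profiles -------------------------------------------------------------
  if ("profiles" %in% stages) {
    all_prof <- c(res$profiles_yoy, res$profiles_embryo)
    res$calls <- call_patterns(all_prof, cfg$thresholds,
                               window = cfg$smoothing_window)
    res$calls$class <- specimens$class[match(res$calls$specimen_id,
                                             specimens$specimen_id)]
    yoy <- res$calls[res$calls$class == "yoy", ]
    if (any(yoy$pattern %in% 1L) && any(yoy$pattern %in% 2L)) {
      res$focus_pb_test <- compare_focus_pb(
        yoy$focus_pbca[yoy$pattern %in% 2L],
        yoy$focus_pbca[yoy$pattern %in% 1L])
      log(sprintf("focus Pb:Ca Pattern2 vs Pattern1: W P = %.3g",
                  res$focus_pb_test$p.value))
    }
    log(sprintf("pattern calls: %d Pattern 1, %d Pattern 2, %d undetermined",
                sum(res$calls$pattern %in% 1L), sum(res$calls$pattern %in% 2L),
                sum(is.na(res$calls$pattern))))
    write_artifact(res$calls, cfg, "pattern_calls.csv", log)
  }

  ## backcalc -------------------------------------------------------------
  if ("backcalc" %in% stages) {
    res$backcalc <- backcalc_shifts(res$calls, specimens, cfg$backcalc)
    p1 <- res$backcalc[!is.na(res$backcalc$l_t_cm), ]
    if (nrow(p1)) {
      log(sprintf("back-calculated L_t: mean %.1f cm (n = %d)",
                  mean(p1$l_t_cm), nrow(p1)))
    }
    write_artifact(res$backcalc, cfg, "backcalc.csv", log)
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(c(sprintf("sharktrace %s | config %s | seed %s",
                         as.character(utils::packageVersion("sharktrace")),
                         config_hash(cfg), cfg$seed), log_lines),
               file.path(cfg$out_dir, "pipeline.log"))
  }
  res$log <- log_lines
  invisible(res)
}
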