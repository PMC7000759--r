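#' Calibrated concentrations for one replicate ablation
#'
#' net cps -> drift-corrected, externally calibrated ppm, then internal
#' standardization: absolute ppm are rescaled so the internal-standard mass
#' equals the assumed Ca mass fraction of the matrix, and element:Ca molar
#' ratios (umol/mol) are formed, which cancels both ablation yield and the
#' Ca-fraction assumption.
#'
#' @param record spot `ablation_record`.
#' @param run `run_sequence` containing its bracketing blanks.
#' @param model `calibration_model`.
#' @return list with `ppm_cal` (externally calibrated, before internal
#'   rescale), `ppm` (internally standardized), `ratio_umol_mol`,
#'   `below_lod` (logical per mass), `lod_ppm`, `n_spikes`.
#' @export
quantify_replicate <- function(record, run, model) {
  config <- model$config
  res <- integrate_signal(record, bracketing_blanks(run, record), config,
                          model$alpha)
  d <- drift_at(model, record$order)
  ppm_cal <- res$net / (model$sensitivity * d)
  ppm_cal[model$uncalibratable] <- NA_real_
  lod <- lod_at(model, record$order)
  is_lab <- config$internal_standard
  if (!is.finite(ppm_cal[[is_lab]]) || ppm_cal[[is_lab]] <= 0) {
    failed_ablation(record$record_id, "internal standard not quantifiable")
  }
  iso <- config$isotopes
  a <- stats::setNames(iso$atomic_mass, iso$label)
  ratio <- (ppm_cal / a[names(ppm_cal)]) /
    (ppm_cal[[is_lab]] / a[[is_lab]]) * 1e6
  ppm <- ppm_cal * (ca_ppm(config) / ppm_cal[[is_lab]])
  list(ppm_cal = ppm_cal, ppm = ppm, ratio_umol_mol = ratio,
       below_lod = ppm_cal < lod, lod_ppm = lod, n_spikes = res$n_spikes)
}

#' Quantify a spot from its replicate ablations
#'
#' Averages the element:Ca ratios and internally standardized ppm across the
#' replicate ablations of one spot (after any exclusions from robust
#' replicate screening) into a single multi-elemental signature. A spot
#' whose replicates are all excluded, or all fail ablation, yields a missing
#' signature (NA values).
#'
#' @param records list of replicate `ablation_record`s sharing specimen and
#'   target.
#' @param run `run_sequence`.
#' @param model `calibration_model`.
#' @param exclude record ids excluded by replicate screening.
#' @return data.frame, one row per monitored mass: `specimen_id`, `target`,
#'   `element`, `ppm`, `ratio_umol_mol`, `below_lod`, `n_replicates`,
#'   `replicates_used`, `replicates_excluded`.
#' @export
quantify_spot <- function(records, run, model, exclude = character(0)) {
  stopifnot(length(records) >= 1)
  spec <- unique(vapply(records, function(r) r$specimen_id, character(1)))
  targ <- unique(vapply(records, function(r) r$target, character(1)))
  if (length(spec) != 1 || length(targ) != 1) {
    stop("replicates must share specimen and target")
  }
  lab <- model$config$isotopes$label
  used <- character(0)
  failed <- character(0)
  reps <- list()
  for (r in records) {
    if (r$record_id %in% exclude) next
    q <- tryCatch(quantify_replicate(r, run, model),
                  sharktrace_failed_ablation = function(e) NULL)
    if (is.null(q)) {
      failed <- c(failed, r$record_id)
    } else {
      reps[[r$record_id]] <- q
      used <- c(used, r$record_id)
    }
  }
  excluded <- c(intersect(vapply(records, `[[`, character(1), "record_id"),
                          exclude), failed)
  if (!length(reps)) {
    return(data.frame(specimen_id = spec, target = targ, element = lab,
                      ppm = NA_real_, ratio_umol_mol = NA_real_,
                      below_lod = NA, n_replicates = 0L,
                      replicates_used = "",
                      replicates_excluded = paste(excluded, collapse = ";"),
                      stringsAsFactors = FALSE))
  }
  ppm <- rowMeans(sapply(reps, function(q) q$ppm[lab]))
  ratio <- rowMeans(sapply(reps, function(q) q$ratio_umol_mol[lab]))
  # a measurement counts as below LOD when most replicates sit below it
  bel <- rowMeans(sapply(reps, function(q) as.numeric(q$below_lod[lab]))) >= 0.5
  data.frame(specimen_id = spec, target = targ, element = lab,
             ppm = as.numeric(ppm), ratio_umol_mol = as.numeric(ratio),
             below_lod = as.logical(bel), n_replicates = length(reps),
             replicates_used = paste(used, collapse = ";"),
             replicates_excluded = paste(excluded, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Stahel-Donoho outlyingness of replicate spot scans
#'
#' Projection-pursuit outlyingness over the pooled replicate ppm vectors of
#' an analysis set: each column is first robustly standardized
#' (median/MAD), then the outlyingness of a replicate is the maximum over
#' seeded random unit projections (plus the coordinate axes) of
#' |x.u - median(X.u)| / MAD(X.u). Projections with zero MAD are skipped.
#' With n = 3 replicates per spot no per-spot covariance exists, so pooling
#' across the whole analysis set is what makes the measure usable.
#'
#' @param x matrix, rows = replicate scans, columns = retained elements
#'   (ppm).
#' @param cutoff replicates with outlyingness > cutoff are excluded
#'   (default 10).
#' @param n_proj number of random projections.
#' @param seed seed for the projection directions.
#' @return list with `outlyingness` (per row, named by rownames) and
#'   `exclude` (row indices exceeding the cutoff).
#' @export
detect_outlier_replicates <- function(x, cutoff = 10, n_proj = 1000,
                                      seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 5) stop("need >= 5 pooled replicate vectors")
  d <- ncol(x)
  med <- apply(x, 2, stats::median)
  madv <- apply(x, 2, stats::mad)
  keep_col <- madv > 0
  z <- sweep(sweep(x[, keep_col, drop = FALSE], 2, med[keep_col]), 2,
             madv[keep_col], `/`)
  if (!ncol(z)) {
    warning("all element scales degenerate; outlyingness undefined")
    return(list(outlyingness = rep(NA_real_, nrow(x)), exclude = integer(0)))
  }
  dz <- ncol(z)
  u <- with_substream(seed, "sd_projections", {
    m <- matrix(rnorm(n_proj * dz), nrow = dz)
    sweep(m, 2, sqrt(colSums(m^2)), `/`)
  })
  u <- cbind(diag(dz), u)
  proj <- z %*% u
  pmed <- apply(proj, 2, stats::median)
  pmad <- apply(proj, 2, stats::mad)
  ok <- pmad > 0
  if (!any(ok)) {
    warning("all projections degenerate; outlyingness undefined")
    return(list(outlyingness = rep(NA_real_, nrow(x)), exclude = integer(0)))
  }
  out <- apply(abs(sweep(proj[, ok, drop = FALSE], 2, pmed[ok])) %*%
                 diag(1 / pmad[ok], sum(ok)), 1, max)
  names(out) <- rownames(x)
  list(outlyingness = out, exclude = which(out > cutoff))
}

#' Drop elements measured below the limit of detection too often
#'
#' An element with at least `threshold` (default 10\%, boundary inclusive)
#' of its measurements below LOD across the analysis set is omitted from
#' every signature.
#'
#' @param signatures long data.frame of signatures (as from
#'   [quantify_spot()] rows bound together) with columns `element`,
#'   `below_lod`.
#' @param threshold inclusive fraction at or above which an element is
#'   dropped.
#' @return list with `retained` (element labels), `dropped` (data.frame of
#'   element and below-LOD fraction) and `signatures` restricted to retained
#'   elements.
#' @export
filter_by_lod <- function(signatures, threshold = 0.10) {
  stopifnot(all(c("element", "below_lod") %in% names(signatures)))
  frac <- tapply(signatures$below_lod, signatures$element,
                 function(v) mean(v, na.rm = TRUE))
  frac[is.na(frac)] <- 1 # elements never quantified are dropped
  dropped <- names(frac)[frac >= threshold]
  retained <- setdiff(unique(signatures$element), dropped)
  if (!length(retained)) stop("all elements fall below the LOD rule")
  list(retained = retained,
       dropped = data.frame(element = dropped,
                            below_lod_fraction = as.numeric(frac[dropped]),
                            stringsAsFactors = FALSE),
       signatures = signatures[signatures$element %in% retained, ,
                               drop = FALSE])
}

#' Reduce all spot ablations of a run to screened element:Ca signatures
#'
#' Orchestrates the spot chain: quantifies every replicate, pools the
#' replicate ppm vectors across the analysis set for Stahel-Donoho
#' screening (outlyingness > `cutoff` excluded), averages the surviving
#' replicates per spot, and applies the below-LOD element filter.
#'
#' @param run `run_sequence`.
#' @param model `calibration_model`.
#' @param cutoff outlyingness exclusion threshold.
#' @param lod_threshold inclusive below-LOD fraction at which an element is
#'   dropped.
#' @param n_proj,seed projection-pursuit settings (seed defaults to the
#'   run's root seed).
#' @return list with `signatures` (long data.frame over retained elements),
#'   `retained`, `dropped`, `outlyingness` (per replicate record),
#'   `excluded_replicates`, `qc` (per-replicate spike counts and LODs).
#' @export
reduce_spots <- function(run, model, cutoff = 10, lod_threshold = 0.10,
                         n_proj = 1000, seed = run$root_seed) {
  if (is.null(seed) || is.na(seed)) seed <- 1L
  man <- run$manifest
  spots <- man[man$role == "spot", , drop = FALSE]
  if (!nrow(spots)) stop("run contains no spot ablations")
  key <- paste(spots$specimen_id, spots$target, sep = "|")

  lab <- model$config$isotopes$label
  quant <- list()
  qc <- list()
  for (id in spots$record_id) {
    q <- tryCatch(quantify_replicate(run$records[[id]], run, model),
                  sharktrace_failed_ablation = function(e) NULL)
    quant[[id]] <- q
    if (!is.null(q)) {
      qc[[id]] <- data.frame(record_id = id,
                             n_spikes = sum(q$n_spikes),
                             stringsAsFactors = FALSE)
    }
  }
  ok_ids <- names(quant)[!vapply(quant, is.null, logical(1))]
  pool <- t(vapply(ok_ids, function(id) quant[[id]]$ppm[lab],
                   numeric(length(lab))))
  rownames(pool) <- ok_ids

  excluded <- character(0)
  outly <- NULL
  if (nrow(pool) >= 5) {
    sd_res <- detect_outlier_replicates(pool, cutoff = cutoff,
                                        n_proj = n_proj, seed = seed)
    outly <- sd_res$outlyingness
    excluded <- rownames(pool)[sd_res$exclude]
  }

  sig <- do.call(rbind, lapply(unique(key), function(k) {
    ids <- spots$record_id[key == k]
    quantify_spot(run$records[ids], run, model, exclude = excluded)
  }))
  flt <- filter_by_lod(sig, lod_threshold)
  list(signatures = flt$signatures, retained = flt$retained,
       dropped = flt$dropped, outlyingness = outly,
       excluded_replicates = excluded,
       qc = if (length(qc)) do.call(rbind, qc) else NULL,
       all_signatures = sig)
}
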