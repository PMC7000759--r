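#' Reduce a transect ablation to a distance-resolved profile
#'
#' Despikes and background-subtracts each mass series over the detected
#' signal window and maps acquisition time to distance from the vertebral
#' focus: distance = scan speed x (t - t_signal_start). If the manifest says
#' the scan started at the distal end (`scan_origin != "focus"`), the
#' profile is reversed so distance 0 is always the focus end. Both net cps
#' (the basis of the raw-ratio profiles) and drift-corrected calibrated ppm
#' are returned.
#'
#' @param record transect `ablation_record`.
#' @param run `run_sequence`.
#' @param model `calibration_model`.
#' @param trim_s seconds trimmed from each end of the signal window.
#' @return object of class `transect_profile`: `specimen_id`,
#'   `distance_um` (non-negative, strictly increasing), `cps` and `ppm`
#'   (points x masses), `n_points`, `resampled = FALSE`.
#' @export
reduce_transect <- function(record, run, model, trim_s = 2) {
  stopifnot(record$role == "transect")
  config <- model$config
  res <- integrate_signal(record, bracketing_blanks(run, record), config,
                          model$alpha, trim_s = trim_s)
  speed <- record$scan_speed_um_s
  if (is.na(speed) || speed <= 0) stop("transect record lacks scan speed")
  tt <- record$time_s[res$window_idx]
  pos <- speed * (tt - res$window_start_raw)
  cps <- res$despiked
  if (!identical(record$scan_origin, "focus")) {
    pos <- max(pos) - pos
    ord <- order(pos)
    pos <- pos[ord]
    cps <- cps[ord, , drop = FALSE]
  }
  d <- drift_at(model, record$order)
  ppm <- sweep(cps, 2, model$sensitivity * d, `/`)
  ppm[, model$uncalibratable] <- NA_real_
  structure(list(specimen_id = record$specimen_id,
                 record_id = record$record_id,
                 distance_um = pos, cps = cps, ppm = ppm,
                 n_points = length(pos), resampled = FALSE),
            class = "transect_profile")
}

#' Resample transect profiles to a common length
#'
#' Linearly interpolates every profile onto the index grid of the longest
#' one so profiles are directly comparable, and builds the multivariate
#' feature matrix used by the distance-based tests: one row per specimen,
#' columns the concatenated resampled per-element sequences. Per-element
#' transect means are returned as the lower-dimensional alternative
#' summary.
#'
#' @param profiles list of `transect_profile` objects.
#' @param elements element labels to keep (default: all shared masses).
#' @param value `"ppm"` or `"cps"`.
#' @return list with `profiles` (resampled), `features` (specimens x
#'   (elements x n_points) matrix), `means` (specimens x elements matrix)
#'   and `n_points`.
#' @export
resample_transects <- function(profiles, elements = NULL,
                               value = c("ppm", "cps")) {
  value <- match.arg(value)
  stopifnot(length(profiles) >= 2)
  for (p in profiles) {
    if (p$n_points < 2) stop("profile ", p$specimen_id, " has < 2 points")
  }
  if (is.null(elements)) {
    elements <- Reduce(intersect, lapply(profiles, function(p) colnames(p$cps)))
  }
  n_max <- max(vapply(profiles, function(p) as.numeric(p$n_points),
                      numeric(1)))
  grid <- seq(0, 1, length.out = n_max)
  res <- lapply(profiles, function(p) {
    src <- seq(0, 1, length.out = p$n_points)
    m <- p[[value]][, elements, drop = FALSE]
    out <- apply(m, 2, function(y) stats::approx(src, y, xout = grid)$y)
    dist_new <- stats::approx(src, p$distance_um, xout = grid)$y
    q <- p
    q$distance_um <- dist_new
    q[[value]] <- out
    other <- setdiff(c("ppm", "cps"), value)
    q[[other]] <- NULL
    q$n_points <- n_max
    q$resampled <- TRUE
    q
  })
  feats <- t(vapply(res, function(p) as.numeric(p[[value]]),
                    numeric(n_max * length(elements))))
  colnames(feats) <- as.vector(outer(seq_len(n_max), elements,
                                     function(i, e) paste0(e, "_", i)))
  rownames(feats) <- vapply(res, function(p) p$specimen_id, character(1))
  means <- t(vapply(res, function(p) colMeans(p[[value]]),
                    numeric(length(elements))))
  dimnames(means) <- list(rownames(feats), elements)
  list(profiles = res, features = feats, means = means, n_points = n_max)
}

#' @export
print.transect_profile <- function(x, ...) {
  cat("Transect profile:", x$specimen_id, "|", x$n_points, "points |",
      sprintf("0-%.0f um from focus", max(x$distance_um)),
      if (x$resampled) "| resampled" else "", "\n")
  invisible(x)
}
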