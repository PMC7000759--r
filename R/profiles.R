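#' Sr:Ba and Pb:Ca ratio profiles from a transect
#'
#' Forms the raw-cps Sr:Ba (salinity proxy: nearshore low, offshore high)
#' and Pb:Ca (contamination indicator) ratios point by point along the
#' distance-from-focus grid, then smooths each with a centered running
#' average (default 11 points). Points with a nonpositive denominator are
#' flagged missing (NA), never infinite, and are excluded from the
#' smoothing windows. Ratios are formed first and smoothed second.
#'
#' @param profile `transect_profile`.
#' @param window odd smoothing window size (points).
#' @param sr,ba,pb,ca mass labels to use.
#' @return object of class `ratio_profile`: `specimen_id`, `distance_um`,
#'   `srba`, `pbca`, `srba_smooth`, `pbca_smooth`, `window`.
#' @export
ratio_profiles <- function(profile, window = 11, sr = "Sr88", ba = "Ba137",
                           pb = "Pb208", ca = "Ca43") {
  stopifnot(inherits(profile, "transect_profile"))
  need <- c(sr, ba, pb, ca)
  if (!all(need %in% colnames(profile$cps))) {
    stop("profile lacks required masses: ",
         paste(setdiff(need, colnames(profile$cps)), collapse = ", "))
  }
  cps <- profile$cps
  safe_ratio <- function(num, den) {
    out <- ifelse(den > 0, num / den, NA_real_)
    out
  }
  srba <- safe_ratio(cps[, sr], cps[, ba])
  pbca <- safe_ratio(cps[, pb], cps[, ca])
  structure(list(specimen_id = profile$specimen_id,
                 distance_um = profile$distance_um,
                 srba = srba, pbca = pbca,
                 srba_smooth = moving_average(srba, window),
                 pbca_smooth = moving_average(pbca, window),
                 window = window),
            class = "ratio_profile")
}

#' Centered running average with symmetric edge shrinkage
#'
#' At interior positions the window is the full `window` points; near the
#' edges it shrinks symmetrically (down to a single point at the ends) so
#' the output has the input's length. Missing points are excluded from the
#' window means.
#'
#' @param x numeric series.
#' @param window odd window size, >= 1.
#' @return smoothed series, same length as `x`.
#' @export
moving_average <- function(x, window = 11) {
  if (window %% 2 == 0) stop("window must be odd")
  if (window < 1) stop("window must be >= 1")
  n <- length(x)
  half <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1, n - i)
    w <- x[(i - h):(i + h)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Default thresholds for migration-pattern classification
#'
#' Taken from the observed ranges of the two gestation classes: Pattern-2
#' profiles sit in the 0-200 nearshore band (`t_low`); Pattern-1 peaks fall
#' in 600-1200 (`t_peak`) and the nearshore return drops the ratio below
#' the 150-400 coastal range (`t_return`). `segment_fraction` defines the
#' initial/terminal segments ("shortly prior to birth") as a fraction of
#' the transect.
#'
#' @param t_low Pattern-2 ceiling on the smoothed Sr:Ba maximum.
#' @param t_peak minimum smoothed Sr:Ba peak for Pattern 1.
#' @param t_return ceiling on the terminal-segment mean for Pattern 1, and
#'   the crossing level used to locate the habitat shift.
#' @param segment_fraction fraction of points forming the initial and
#'   terminal segments.
#' @return named list of thresholds.
#' @export
pattern_thresholds <- function(t_low = 200, t_peak = 600, t_return = 400,
                               segment_fraction = 0.10) {
  stopifnot(t_low > 0, t_peak > t_low, t_return > 0,
            segment_fraction > 0, segment_fraction < 0.5)
  list(t_low = t_low, t_peak = t_peak, t_return = t_return,
       segment_fraction = segment_fraction)
}

segment_idx <- function(n, fraction, where = c("head", "tail", "mid")) {
  where <- match.arg(where)
  k <- max(1L, floor(n * fraction))
  switch(where,
         head = seq_len(k),
         tail = (n - k + 1L):n,
         mid = max(1L, floor(0.25 * n)):min(n, ceiling(0.75 * n)))
}

#' Classify the gestation migration pattern of a profile
#'
#' Rule-based call on the smoothed Sr:Ba profile:
#' \itemize{
#'   \item Pattern 2 (nearshore residency) if the maximum stays at or below
#'     `t_low`;
#'   \item Pattern 1 (offshore excursion with nearshore return) if the
#'     maximum reaches `t_peak` and the terminal-segment mean has fallen to
#'     `t_return` or below;
#'   \item undetermined otherwise: profiles between the two envelopes get
#'     an explicit third class instead of a forced binary call.
#' }
#' Pb:Ca corroboration: for Pattern 1, a terminal-segment mean above the
#' mid-gestation (25-75\%) mean; for Pattern 2, an initial-segment mean
#' above the mid-gestation mean (elevated Pb at the beginning of
#' gestation).
#'
#' @param rp `ratio_profile` (transect of >= 50 points).
#' @param thresholds [pattern_thresholds()].
#' @return object of class `pattern_call`: `specimen_id`, `pattern`
#'   (integer 1/2 or NA for undetermined), `peak_srba`, `terminal_srba`,
#'   `focus_srba`, `r_t_um` (Pattern 1 shift distance, else NA),
#'   `pb_corroborated`, `thresholds`.
#' @export
classify_pattern <- function(rp, thresholds = pattern_thresholds()) {
  stopifnot(inherits(rp, "ratio_profile"))
  s <- rp$srba_smooth
  if (all(is.na(s))) stop("all Sr:Ba points missing")
  n <- length(s)
  if (n < 50) stop("transect too short to classify (< 50 points)")
  tf <- thresholds$segment_fraction
  peak <- max(s, na.rm = TRUE)
  term <- mean(s[segment_idx(n, tf, "tail")], na.rm = TRUE)
  foc <- mean(s[segment_idx(n, tf, "head")], na.rm = TRUE)
  pb_mid <- mean(rp$pbca_smooth[segment_idx(n, tf, "mid")], na.rm = TRUE)
  pb_term <- mean(rp$pbca_smooth[segment_idx(n, tf, "tail")], na.rm = TRUE)
  pb_head <- mean(rp$pbca_smooth[segment_idx(n, tf, "head")], na.rm = TRUE)

  if (peak <= thresholds$t_low) {
    pattern <- 2L
    r_t <- NA_real_
    pb_ok <- isTRUE(pb_head > pb_mid)
  } else if (peak >= thresholds$t_peak && term <= thresholds$t_return) {
    pattern <- 1L
    r_t <- detect_shift(rp, thresholds)
    pb_ok <- isTRUE(pb_term > pb_mid)
  } else {
    pattern <- NA_integer_
    r_t <- NA_real_
    pb_ok <- NA
  }
  structure(list(specimen_id = rp$specimen_id, pattern = pattern,
                 peak_srba = peak, terminal_srba = term, focus_srba = foc,
                 r_t_um = r_t, pb_corroborated = pb_ok,
                 thresholds = thresholds),
            class = "pattern_call")
}

#' Locate the maternal habitat shift on a Pattern-1 profile
#'
#' The shift distance R_t is the distance from the focus of the first point
#' after the global smoothed Sr:Ba maximum at which the smoothed ratio
#' falls below `t_return` (the return into the nearshore 150-400 band).
#'
#' @param rp `ratio_profile`.
#' @param thresholds [pattern_thresholds()].
#' @return R_t in um from the focus.
#' @export
detect_shift <- function(rp, thresholds = pattern_thresholds()) {
  s <- rp$srba_smooth
  i_peak <- which.max(s)
  if (s[i_peak] < thresholds$t_return) {
    stop("no crossing: the Sr:Ba maximum never reaches t_return ",
         "(inconsistent with a Pattern-1 call)")
  }
  after <- which(seq_along(s) > i_peak & !is.na(s) & s < thresholds$t_return)
  if (!length(after)) {
    stop("no crossing below t_return after the Sr:Ba maximum ",
         "(inconsistent with a Pattern-1 call)")
  }
  rp$distance_um[after[1]]
}

#' Call migration patterns for a set of transect profiles
#'
#' @param profiles list of `transect_profile` objects.
#' @param thresholds [pattern_thresholds()].
#' @param window smoothing window.
#' @return data.frame, one row per profile: `specimen_id`, `pattern`
#'   (`"1"`, `"2"` or `"undetermined"` in `pattern_label`), `peak_srba`,
#'   `terminal_srba`, `focus_srba`, `r_t_um`, `pb_corroborated`,
#'   `transect_um`, `focus_pbca` (initial-segment mean Pb:Ca).
#' @export
call_patterns <- function(profiles, thresholds = pattern_thresholds(),
                          window = 11) {
  rows <- lapply(profiles, function(p) {
    rp <- ratio_profiles(p, window)
    call <- classify_pattern(rp, thresholds)
    n <- length(rp$srba_smooth)
    head_i <- segment_idx(n, thresholds$segment_fraction, "head")
    data.frame(specimen_id = call$specimen_id,
               pattern = call$pattern,
               pattern_label = if (is.na(call$pattern)) "undetermined" else
                 as.character(call$pattern),
               peak_srba = call$peak_srba,
               terminal_srba = call$terminal_srba,
               focus_srba = call$focus_srba,
               r_t_um = call$r_t_um,
               pb_corroborated = call$pb_corroborated,
               transect_um = max(p$distance_um),
               focus_pbca = mean(rp$pbca_smooth[head_i], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank-sum comparison of focus-segment Pb:Ca between pattern groups
#'
#' Convenience utility (two-sided Mann-Whitney/Wilcoxon rank-sum test)
#' comparing the initial-segment mean Pb:Ca of two groups of profiles,
#' e.g. Pattern-2 versus Pattern-1 specimens.
#'
#' @param focus_pb_1,focus_pb_2 numeric vectors of focus-segment mean Pb:Ca
#'   for the two groups (both nonempty).
#' @return `htest` from [stats::wilcox.test()] (exact where possible).
#' @export
compare_focus_pb <- function(focus_pb_1, focus_pb_2) {
  if (!length(focus_pb_1) || !length(focus_pb_2)) {
    stop("both groups must be nonempty")
  }
  if (length(focus_pb_1) < 2 || length(focus_pb_2) < 2) {
    warning("group of size 1: rank-sum test is uninformative")
  }
  stats::wilcox.test(focus_pb_1, focus_pb_2, exact = TRUE)
}

#' @export
print.pattern_call <- function(x, ...) {
  lab <- if (is.na(x$pattern)) "undetermined" else paste("Pattern", x$pattern)
  cat(sprintf("%s: %s | peak Sr:Ba %.0f, terminal %.0f",
              x$specimen_id, lab, x$peak_srba, x$terminal_srba))
  if (!is.na(x$r_t_um)) cat(sprintf(" | shift at %.0f um", x$r_t_um))
  if (!is.na(x$pb_corroborated)) {
    cat(" | Pb:Ca", if (x$pb_corroborated) "corroborates" else
      "does not corroborate")
  }
  cat("\n")
  invisible(x)
}
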