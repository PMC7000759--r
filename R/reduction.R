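#' Critical value of the two-sided Grubbs outlier test
#'
#' Closed form from the t distribution:
#' G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2)) with
#' t = qt(1 - alpha/(2n), n - 2).
#'
#' @param n sample size (>= 3).
#' @param alpha significance level.
#' @return critical value of G = max|x - mean| / sd.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3, alpha > 0, alpha < 1)
  t <- stats::qt(1 - alpha / (2 * n), n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterative Grubbs despiking of a cps series
#'
#' Repeatedly applies the two-sided Grubbs test to the non-spike points,
#' flagging the single most extreme point whenever its statistic exceeds the
#' critical value, until no point is flagged. Flagged spikes are replaced by
#' the mean of the remaining points, matching the convention of replacing
#' detected spikes with mean values. Fully deterministic (ties resolve to
#' the first index).
#'
#' @param x numeric series (cps).
#' @param alpha significance level of each Grubbs test.
#' @return list with `series` (despiked, same length) and `spikes`
#'   (integer indices of replaced points).
#' @export
#' @examples
#' despike_grubbs(c(10, 10, 10, 10, 100))$series
despike_grubbs <- function(x, alpha = 0.05) {
  stopifnot(is.numeric(x), alpha > 0, alpha < 1)
  n <- length(x)
  if (n < 3) {
    warning("series shorter than 3 points; returned unchanged")
    return(list(series = x, spikes = integer(0)))
  }
  keep <- !is.na(x)
  spikes <- integer(0)
  repeat {
    idx <- which(keep)
    m <- length(idx)
    if (m < 3) break
    mu <- mean(x[idx])
    s <- stats::sd(x[idx])
    if (!is.finite(s) || s <= 0) break
    dev <- abs(x[idx] - mu)
    i_max <- idx[which.max(dev)]
    g <- max(dev) / s
    if (g > grubbs_critical(m, alpha)) {
      keep[i_max] <- FALSE
      spikes <- c(spikes, i_max)
    } else {
      break
    }
  }
  out <- x
  if (length(spikes)) out[spikes] <- mean(x[keep], na.rm = TRUE)
  list(series = out, spikes = sort(spikes))
}

#' Per-mass gas-blank statistics from bracketing blank records
#' @keywords internal
blank_stats <- function(blanks) {
  stopifnot(length(blanks) >= 1)
  mats <- lapply(blanks, function(b) b$cps)
  pooled <- do.call(rbind, mats)
  list(mean = colMeans(pooled),
       sd = apply(pooled, 2, stats::sd))
}

#' Locate the gas blanks bracketing a record in a run
#' @keywords internal
bracketing_blanks <- function(run, record) {
  man <- run$manifest
  is_blank <- man$role == "gas_blank"
  before <- man$record_id[is_blank & man$order < record$order]
  after <- man$record_id[is_blank & man$order > record$order]
  out <- list()
  if (length(before)) out$before <- run$records[[before[length(before)]]]
  if (length(after)) out$after <- run$records[[after[1]]]
  if (!length(out)) stop("no gas blanks bracket record ", record$record_id)
  out
}

#' Condition signalling an ablation with no detectable signal plateau
#' @keywords internal
failed_ablation <- function(record_id, msg) {
  stop(structure(class = c("sharktrace_failed_ablation", "error", "condition"),
                 list(message = paste0("failed ablation ", record_id, ": ", msg),
                      call = NULL)))
}

#' Integrate one ablation record to net mean cps per mass
#'
#' Automates the manual signal screening of time-resolved LA-ICP-MS data:
#' the signal window is the longest contiguous region where the
#' internal-standard cps exceed blank mean + 10 x blank SD, trimmed by
#' `trim_s` seconds at each end (an explicit `window` of times overrides the
#' detection). Within the window each mass series is despiked by the
#' iterative Grubbs test, then the mean of the bracketing gas blanks is
#' subtracted. Net values may be negative; they are kept (not clamped) so
#' that below-LOD bookkeeping stays unbiased.
#'
#' @param record `ablation_record`.
#' @param blanks list of bracketing gas-blank records (1 or 2).
#' @param config [mass_config()].
#' @param alpha Grubbs significance level.
#' @param trim_s seconds trimmed from each end of the detected window.
#' @param window optional numeric length-2 vector of start/end times (s)
#'   overriding plateau detection.
#' @return list with `net` (named net mean cps), `blank_mean`, `blank_sd`,
#'   `window_idx`, `window_time`, `n_spikes` (named count per mass),
#'   `despiked` (window x mass matrix of despiked, background-subtracted cps).
#' @export
integrate_signal <- function(record, blanks, config, alpha = 0.05,
                             trim_s = 2, window = NULL) {
  stopifnot(inherits(record, "ablation_record"))
  bs <- blank_stats(blanks)
  lab <- colnames(record$cps)
  is_lab <- config$internal_standard
  if (!is_lab %in% lab) stop("internal standard missing from record")
  if (is.null(window)) {
    thr <- bs$mean[[is_lab]] + 10 * bs$sd[[is_lab]]
    above <- record$cps[, is_lab] > thr
    runs <- rle(above)
    if (!any(runs$values)) {
      failed_ablation(record$record_id,
                      "internal-standard signal never exceeds blank + 10 SD")
    }
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    k <- which(runs$values)[which.max(runs$lengths[runs$values])]
    w0 <- starts[k]
    w1 <- ends[k]
    rate <- 1 / stats::median(diff(record$time_s))
    trim <- round(trim_s * rate)
    wi <- (w0 + trim):(w1 - trim)
    if (length(wi) < 1 || (w1 - trim) < (w0 + trim)) {
      failed_ablation(record$record_id, "signal window empty after trimming")
    }
  } else {
    wi <- which(record$time_s >= window[1] & record$time_s <= window[2])
    if (!length(wi)) failed_ablation(record$record_id, "explicit window empty")
    w0 <- wi[1]
  }
  desp <- matrix(NA_real_, nrow = length(wi), ncol = length(lab),
                 dimnames = list(NULL, lab))
  n_spikes <- stats::setNames(integer(length(lab)), lab)
  for (el in lab) {
    d <- despike_grubbs(record$cps[wi, el], alpha)
    desp[, el] <- d$series - bs$mean[[el]]
    n_spikes[el] <- length(d$spikes)
  }
  list(net = colMeans(desp), blank_mean = bs$mean, blank_sd = bs$sd,
       window_idx = wi, window_time = record$time_s[range(wi)],
       window_start_raw = record$time_s[w0],
       n_spikes = n_spikes, despiked = desp)
}
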