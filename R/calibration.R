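#' Build the calibration model from a run's standards and blanks
#'
#' Uses the bracketing NIST-612 ablations for external calibration and
#' drift correction, and the pooled gas blanks for limits of detection:
#' \itemize{
#'   \item sensitivity S (cps per ppm) per mass from the first standard
#'     bracket (mean net cps across its replicates / reference ppm);
#'   \item drift factor d(order) per mass = linear interpolation, on
#'     acquisition order, of each standard ablation's net cps relative to
#'     the first bracket's mean response, between the two nearest
#'     bracketing standards (constant extrapolation outside);
#'   \item LOD(ppm, order) = 3 x SD(pooled blank cps) / (S x d(order)).
#' }
#' Masses whose standard net cps are not positive in every bracket are
#' flagged uncalibratable and excluded from quantification.
#'
#' @param run `run_sequence`.
#' @param config [mass_config()]; defaults to the run's own config.
#' @param alpha Grubbs significance level used when integrating standards.
#' @return object of class `calibration_model`.
#' @export
build_drift_model <- function(run, config = run$config, alpha = 0.05) {
  man <- run$manifest
  std_ids <- man$record_id[man$role == "nist612"]
  if (length(std_ids) < 2) stop("need >= 2 calibration standard ablations")
  lab <- config$isotopes$label
  nist_ppm <- stats::setNames(config$isotopes$nist612_ppm,
                              config$isotopes$label)

  nets <- list()
  orders <- integer(0)
  brackets <- integer(0)
  prev_order <- -Inf
  prev_bracket <- 0L
  for (id in std_ids) {
    rec <- run$records[[id]]
    res <- integrate_signal(rec, bracketing_blanks(run, rec), config, alpha)
    nets[[id]] <- res$net
    orders <- c(orders, rec$order)
    b <- rec$std_bracket
    if (is.null(b) || is.na(b)) {
      # infer: replicates separated only by a blank share a bracket
      b <- if (rec$order - prev_order <= 2) prev_bracket else prev_bracket + 1L
    }
    brackets <- c(brackets, b)
    prev_order <- rec$order
    prev_bracket <- b
  }
  net_mat <- do.call(rbind, nets)

  bl <- sort(unique(brackets))
  bracket_net <- t(vapply(bl, function(b) {
    colMeans(net_mat[brackets == b, , drop = FALSE])
  }, numeric(length(lab))))
  colnames(bracket_net) <- lab

  uncal <- lab[apply(bracket_net <= 0, 2, any) | apply(net_mat <= 0, 2, any)]
  sens <- bracket_net[1, ] / nist_ppm[lab]
  # drift knots are the individual standard ablations, relative to the
  # first-bracket mean response; linear interpolation between the two
  # nearest bracketing standards, constant outside
  rel <- sweep(net_mat, 2, bracket_net[1, ], `/`)

  blank_ids <- man$record_id[man$role == "gas_blank"]
  if (!length(blank_ids)) stop("run contains no gas blanks")
  bs <- blank_stats(run$records[blank_ids])

  structure(list(sensitivity = sens,
                 bracket_order = orders,
                 bracket_rel = rel,
                 blank_mean = bs$mean, blank_sd = bs$sd,
                 lod_ref_ppm = 3 * bs$sd / pmax(sens, .Machine$double.eps),
                 uncalibratable = uncal,
                 config = config, alpha = alpha),
            class = "calibration_model")
}

#' Per-mass drift factors at an acquisition order
#'
#' Linear interpolation of the relative standard response between the two
#' nearest bracketing standards; constant extrapolation outside.
#'
#' @param model `calibration_model`.
#' @param order acquisition order (scalar).
#' @return named numeric vector of drift factors (1 = first bracket).
#' @export
drift_at <- function(model, order) {
  lab <- colnames(model$bracket_rel)
  if (length(model$bracket_order) == 1L) {
    return(stats::setNames(rep(1, length(lab)), lab))
  }
  out <- vapply(lab, function(el) {
    stats::approx(model$bracket_order, model$bracket_rel[, el],
                  xout = order, rule = 2)$y
  }, numeric(1))
  stats::setNames(out, lab)
}

#' Limits of detection (ppm) at an acquisition order
#'
#' LOD = 3 x SD of the pooled gas-blank cps, converted to concentration by
#' the drift-corrected sensitivity.
#'
#' @inheritParams drift_at
#' @return named numeric vector of LODs in ppm (NA for uncalibratable masses).
#' @export
lod_at <- function(model, order) {
  d <- drift_at(model, order)
  lod <- 3 * model$blank_sd / (model$sensitivity * d)
  lod[model$uncalibratable] <- NA_real_
  lod
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Calibration model:", length(x$bracket_order), "standard ablations,",
      length(x$sensitivity), "masses\n")
  if (length(x$uncalibratable)) {
    cat("  uncalibratable:", paste(x$uncalibratable, collapse = ", "), "\n")
  }
  drift_range <- range(x$bracket_rel)
  cat(sprintf("  drift factors span %.3f-%.3f across brackets\n",
              drift_range[1], drift_range[2]))
  invisible(x)
}
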