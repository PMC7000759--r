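#' Write a run sequence to a directory of CSV files
#'
#' One RFC-4180 CSV per ablation (`time_s` plus one cps column per
#' monitored mass), a `manifest.csv` describing every record, and
#' optionally `specimens.csv` and `truth.csv` when a specimen table /
#' ground truth is supplied. All files are UTF-8 with "." as the decimal
#' separator.
#'
#' @param run `run_sequence`.
#' @param dir output directory (created if missing).
#' @param specimens optional specimen data.frame.
#' @param truth optional `synthetic_truth`; a specimen-level summary
#'   (pattern, shift fraction, radius) is written, not raw per-record
#'   truth.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir, specimens = NULL, truth = NULL) {
  stopifnot(inherits(run, "run_sequence"))
  dir.create(file.path(dir, "records"), recursive = TRUE, showWarnings = FALSE)
  for (rec in run$records) {
    df <- data.frame(time_s = rec$time_s, rec$cps, check.names = FALSE)
    utils::write.csv(df, file.path(dir, "records",
                                   paste0(rec$record_id, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(run$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(specimens)) {
    utils::write.csv(specimens, file.path(dir, "specimens.csv"),
                     row.names = FALSE)
  }
  if (!is.null(truth)) {
    tr <- truth$specimens
    tr$pattern <- NA_integer_
    tr$shift_fraction <- NA_real_
    if (length(truth$yoy_pattern)) {
      i <- match(names(truth$yoy_pattern), tr$specimen_id)
      tr$pattern[i] <- truth$yoy_pattern
      tr$shift_fraction[i] <- truth$yoy_shift_fraction
    }
    utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a run sequence from a manifest and data directory
#'
#' Loads and validates the CSV layout written by [write_run()] (the same
#' schema is accepted for real instrument exports): every record referenced
#' by the manifest must exist, carry `time_s` plus all monitored mass
#' columns, have a known role and a unique id, and the run must contain
#' calibration standards and gas blanks.
#'
#' @param manifest_path path to `manifest.csv`.
#' @param data_dir directory holding the per-record CSVs (default: a
#'   `records/` directory next to the manifest).
#' @param config [mass_config()] naming the monitored masses.
#' @return `run_sequence`.
#' @export
read_run <- function(manifest_path, data_dir = NULL, config = mass_config()) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  if (is.null(data_dir)) data_dir <- file.path(dirname(manifest_path),
                                               "records")
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need_cols <- c("record_id", "role", "specimen_id", "target", "replicate",
                 "order")
  miss <- setdiff(need_cols, names(man))
  if (length(miss)) stop("manifest lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(man$record_id)) {
    stop("duplicate record id(s): ",
         paste(unique(man$record_id[duplicated(man$record_id)]),
               collapse = ", "))
  }
  roles <- c("gas_blank", "nist612", "macs3", "spot", "transect")
  bad <- setdiff(unique(man$role), roles)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (!any(man$role == "nist612")) stop("no calibration standards in run")
  if (!any(man$role == "gas_blank")) stop("no gas blanks in run")
  man <- man[order(man$order), , drop = FALSE]
  lab <- config$isotopes$label
  opt <- function(row, col, default) {
    if (col %in% names(man)) row[[col]] else default
  }
  records <- lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    f <- file.path(data_dir, paste0(row$record_id, ".csv"))
    if (!file.exists(f)) stop("record file missing: ", f)
    df <- utils::read.csv(f, check.names = FALSE)
    miss <- setdiff(c("time_s", lab), names(df))
    if (length(miss)) {
      stop("record ", row$record_id, " lacks column(s): ",
           paste(miss, collapse = ", "))
    }
    if (is.unsorted(df$time_s, strictly = TRUE)) {
      stop("record ", row$record_id, ": time grid not strictly increasing")
    }
    structure(list(record_id = row$record_id, role = row$role,
                   specimen_id = row$specimen_id, target = row$target,
                   replicate = row$replicate, order = as.integer(row$order),
                   slide = opt(row, "slide", NA_integer_),
                   std_bracket = opt(row, "std_bracket", NA_integer_),
                   time_s = df$time_s,
                   cps = as.matrix(df[, lab, drop = FALSE]),
                   spot_um = opt(row, "spot_um", NA_real_),
                   scan_speed_um_s = opt(row, "scan_speed_um_s", NA_real_),
                   scan_length_um = opt(row, "scan_length_um", NA_real_),
                   scan_origin = opt(row, "scan_origin", NA_character_),
                   signal_window_s = c(NA_real_, NA_real_)),
              class = "ablation_record")
  })
  run_sequence(records, config)
}
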