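# Reading and writing recordings and tables.
#
# Recordings travel as CSV with the fixed header
# time_s,bp_mmhg,mcav_cms,pcav_cms,petco2_mmhg plus a YAML sidecar holding
# the labels (participant, sex, stage, ssm_frequency_hz, seed).

recording_columns <- c("time_s", "bp_mmhg", "mcav_cms", "pcav_cms",
                       "petco2_mmhg")

#' Write a recording to CSV (plus optional YAML sidecar)
#'
#' @param rec A `raw_recording` with all four channels.
#' @param path Output CSV path.
#' @param meta_path Optional sidecar path; defaults to `path` with a
#'   `.yaml` extension. Set `NA` to skip the sidecar.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, meta_path = NULL) {
  validate_recording(rec)
  df <- data.frame(time_s = rec$time, bp_mmhg = rec$bp,
                   mcav_cms = rec$mcav, pcav_cms = rec$pcav,
                   petco2_mmhg = rec$petco2)
  write.csv(df, path, row.names = FALSE)
  if (is.null(meta_path)) meta_path <- sub("\\.csv$", ".yaml", path)
  if (!is.na(meta_path)) {
    meta <- rec$labels
    meta$sample_rate_hz <- rec$sample_rate
    yaml::write_yaml(meta, meta_path)
  }
  invisible(path)
}

#' Read a recording from CSV
#'
#' Validates the header, uniform sampling (1e-6 s tolerance), finiteness
#' and positive pressures; errors carry classes `dcatfa_missing_column`,
#' `dcatfa_nonmonotone_time`, `dcatfa_nonuniform_sampling`,
#' `dcatfa_nonfinite`.
#'
#' @param path CSV path (header as written by [write_recording()]).
#' @param meta_path Optional YAML sidecar with labels.
#' @return A `raw_recording`.
#' @export
read_recording <- function(path, meta_path = NULL) {
  df <- read.csv(path)
  missing <- setdiff(recording_columns, names(df))
  if (length(missing) > 0L)
    stop_dcatfa(paste("missing column(s):", paste(missing, collapse = ", ")),
                "dcatfa_missing_column")
  time <- df$time_s
  if (any(!is.finite(as.matrix(df[recording_columns]))))
    stop_dcatfa("non-finite values in recording", "dcatfa_nonfinite")
  if (any(diff(time) <= 0))
    stop_dcatfa("time column not strictly increasing",
                "dcatfa_nonmonotone_time")
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-6)
    stop_dcatfa("non-uniform sampling beyond 1e-6 s tolerance",
                "dcatfa_nonuniform_sampling")
  if (any(df$bp_mmhg <= 0))
    stop_dcatfa("non-positive blood pressure values", "dcatfa_nonfinite")
  labels <- list()
  if (is.null(meta_path)) {
    cand <- sub("\\.csv$", ".yaml", path)
    if (file.exists(cand)) meta_path <- cand
  }
  if (!is.null(meta_path) && file.exists(meta_path))
    labels <- yaml::read_yaml(meta_path)
  new_raw_recording(time - time[1], bp = df$bp_mmhg, mcav = df$mcav_cms,
                    pcav = df$pcav_cms, petco2 = df$petco2_mmhg,
                    sample_rate = 1 / mean(dt), labels = labels)
}

#' Write the cohort ground-truth table as TSV
#'
#' @param truth Truth data frame from [generate_cohort()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
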