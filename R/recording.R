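# RawRecording container: a uniformly sampled multichannel trace.

new_raw_recording <- function(time, bp = NULL, mcav = NULL, pcav = NULL,
                              petco2 = NULL, sample_rate, labels = list()) {
  structure(list(time = time, bp = bp, mcav = mcav, pcav = pcav,
                 petco2 = petco2, sample_rate = sample_rate, labels = labels),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  chans <- c("bp", "mcav", "pcav", "petco2")
  present <- chans[!vapply(x[chans], is.null, logical(1))]
  dur <- length(x$time) / x$sample_rate
  cat(sprintf("<raw_recording> %.1f s @ %g Hz, channels: %s\n",
              dur, x$sample_rate, paste(present, collapse = ", ")))
  if (length(x$labels))
    cat("  labels:", paste(names(x$labels), unlist(x$labels),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

validate_recording <- function(rec) {
  if (!inherits(rec, "raw_recording"))
    stop_dcatfa("not a raw_recording", "dcatfa_invalid_argument")
  n <- length(rec$time)
  for (ch in c("bp", "mcav", "pcav", "petco2")) {
    v <- rec[[ch]]
    if (!is.null(v)) {
      if (length(v) != n)
        stop_dcatfa(sprintf("channel `%s` length differs from time grid", ch),
                    "dcatfa_invalid_argument")
      if (any(!is.finite(v)))
        stop_dcatfa(sprintf("channel `%s` contains non-finite values", ch),
                    "dcatfa_nonfinite")
    }
  }
  dt <- diff(rec$time)
  if (any(dt <= 0)) stop_dcatfa("time not strictly increasing",
                                "dcatfa_nonmonotone_time")
  if (any(abs(dt - 1 / rec$sample_rate) > 1e-6))
    stop_dcatfa("time grid not uniform at the stated sample rate",
                "dcatfa_nonuniform_sampling")
  invisible(rec)
}
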