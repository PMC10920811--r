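#' The seven-band analysis grid
#'
#' Frequency bands used throughout the package: theta1 (4-6 Hz), theta2
#' (6-8 Hz), alpha1 (8-10 Hz), alpha2 (10-12 Hz), beta1 (12-16 Hz), beta2
#' (16-20 Hz) and beta3 (20-24 Hz). Together they cover 4-24 Hz without
#' overlap, so band powers over the grid partition the power in that range.
#'
#' @return A data frame with columns `name`, `low` and `high` (Hz).
#' @export
#' @examples
#' default_bands()
default_bands <- function() {
  data.frame(
    name = c("theta1", "theta2", "alpha1", "alpha2", "beta1", "beta2", "beta3"),
    low  = c(4, 6, 8, 10, 12, 16, 20),
    high = c(6, 8, 10, 12, 16, 20, 24),
    stringsAsFactors = FALSE
  )
}

# Internal: validate a band table, optionally against a sampling rate.
validate_bands <- function(bands, fs = NULL) {
  if (!is.data.frame(bands) || !all(c("name", "low", "high") %in% names(bands)))
    stop_invalid("`bands` must be a data frame with columns name, low, high")
  if (anyDuplicated(bands$name))
    stop_invalid("band names must be unique")
  if (any(bands$low <= 0) || any(bands$high <= bands$low))
    stop_invalid("band edges must satisfy 0 < low < high")
  if (!is.null(fs) && any(bands$high >= fs / 2))
    stop_invalid("band edge at or above the Nyquist frequency (fs/2 = ",
                 fs / 2, " Hz)")
  bands
}
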