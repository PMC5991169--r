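#' Canonical EEG frequency bands
#'
#' Returns the band set used throughout the package: the broadband 1--30 Hz
#' range ("full") plus the five classical sub-bands. Band-limited waveforms
#' are obtained from these definitions with [bandpass_fir()].
#'
#' @param names optional character vector restricting the result to a subset
#'   of band names.
#' @return A data.frame with columns `name`, `low`, `high` (Hz).
#' @examples
#' canonical_bands()
#' @export
canonical_bands <- function(names = NULL) {
  bands <- data.frame(
    name = c("full", "delta", "theta", "alpha1", "alpha2", "beta"),
    low  = c(1, 1, 4, 8, 11, 14),
    high = c(30, 3, 7, 10, 13, 30),
    stringsAsFactors = FALSE
  )
  if (is.null(names)) return(bands)
  missing <- setdiff(names, bands$name)
  if (length(missing) > 0)
    stop_painlep("unknown band name(s): %s", paste(missing, collapse = ", "))
  bands[match(names, bands$name), , drop = FALSE]
}

# Validate a band definition against a sampling rate.
check_band <- function(low, high, sampling_rate) {
  if (!(low > 0 && low < high && high <= sampling_rate / 2))
    stop_painlep("invalid band edges [%g, %g] Hz for sampling rate %g Hz (need 0 < low < high <= Nyquist)",
                 low, high, sampling_rate)
  invisible(TRUE)
}
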