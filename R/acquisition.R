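#' Acquisition configuration
#'
#' Bundles the spectral and temporal geometry of the simulated instrument:
#' the spectral channel grid, the TCSPC time window and binning, and the width
#' of the Gaussian instrument response function (IRF). The 12.5 ns default
#' window is the repetition period of an 80 MHz pulsed laser; 256 time bins
#' and a 0.2 ns IRF FWHM are typical of hybrid-detector TCSPC hardware.
#'
#' @param n_channels,first_center,channel_spacing Spectral grid, as in
#'   [spectral_channels()].
#' @param time_window TCSPC window length in ns (> 0).
#' @param n_time_bins Number of TCSPC histogram bins (>= 8).
#' @param irf_fwhm Full width at half maximum of the Gaussian IRF, in ns.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(n_channels = 16L, first_center = 447.5,
                               channel_spacing = 12.5, time_window = 12.5,
                               n_time_bins = 256L, irf_fwhm = 0.2) {
  n_time_bins <- as.integer(n_time_bins)
  if (n_time_bins < 8L) stop("need at least 8 time bins")
  if (time_window <= 0) stop("time window must be positive")
  if (irf_fwhm < 0) stop("IRF fwhm must be nonnegative")
  channels <- spectral_channels(n_channels, first_center, channel_spacing)
  structure(
    list(
      channels = channels,
      time_window = time_window,
      n_time_bins = n_time_bins,
      bin_width = time_window / n_time_bins,
      irf_fwhm = irf_fwhm
    ),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "<acquisition_config> %d channels (%.1f-%.1f nm), %d bins over %.2f ns, IRF %.2f ns\n",
    x$channels$n_channels, x$channels$centers[1],
    max(x$channels$centers), x$n_time_bins, x$time_window, x$irf_fwhm
  ))
  invisible(x)
}

#' Time-bin centers of an acquisition configuration
#'
#' @param config An [acquisition_config()].
#' @return Numeric vector of bin-center times in ns.
#' @export
time_bin_centers <- function(config) {
  (seq_len(config$n_time_bins) - 0.5) * config$bin_width
}

#' Discretized Gaussian instrument response kernel
#'
#' Samples a Gaussian of the requested FWHM on the acquisition time grid and
#' normalizes it to unit sum. The kernel mean sits at 4 sigma from the window
#' start so the left tail is not clipped. A zero FWHM yields a discrete delta
#' in the first bin.
#'
#' @param fwhm Full width at half maximum, in ns (>= 0).
#' @param config An [acquisition_config()] providing the time grid.
#' @return Numeric vector of length `n_time_bins` summing to 1.
#' @export
gaussian_irf <- function(fwhm, config = acquisition_config()) {
  if (fwhm < 0) stop("IRF fwhm must be nonnegative")
  t <- time_bin_centers(config)
  if (fwhm == 0) {
    k <- numeric(length(t))
    k[1] <- 1
    return(k)
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  mu <- 4 * sigma
  k <- exp(-(t - mu)^2 / (2 * sigma^2))
  k / sum(k)
}
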