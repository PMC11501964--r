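#' Spectral channel map
#'
#' Describes the detector's spectral channel grid: a fixed number of uniformly
#' spaced emission bands, each identified by its center wavelength. The default
#' matches a 16-anode PMT spectrometer with centers running from 447.5 nm to
#' 635 nm in 12.5 nm steps (half width +/- 6.25 nm). Three channels have
#' conventional roles: channel 2 (460 nm) collects second-harmonic generation
#' (SHG) from collagen at 920 nm excitation, channel 7 (522.5 nm) is the
#' two-photon excited fluorescence (TPEF) intensity maximum, and channel 4
#' (485 nm) is the short-wavelength TPEF band used in the spectral ratio.
#'
#' @param n_channels Number of spectral channels (>= 2).
#' @param first_center Center wavelength of channel 1, in nm.
#' @param spacing Uniform channel spacing, in nm.
#' @param half_width Half width of each band, in nm. Defaults to `spacing / 2`.
#' @param shg_channel,ratio_num_channel,tpef_max_channel 1-based indices of the
#'   SHG, ratio-numerator and TPEF-maximum channels.
#'
#' @return An object of class `spectral_channels` with the channel centers.
#' @examples
#' ch <- spectral_channels()
#' channel_center(7, ch)  # 522.5 nm
#' @export
spectral_channels <- function(n_channels = 16L, first_center = 447.5,
                              spacing = 12.5, half_width = spacing / 2,
                              shg_channel = 2L, ratio_num_channel = 4L,
                              tpef_max_channel = 7L) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 2L) stop("need at least 2 spectral channels")
  if (spacing <= 0) stop("channel spacing must be positive")
  centers <- first_center + (seq_len(n_channels) - 1) * spacing
  structure(
    list(
      n_channels = n_channels,
      centers = centers,
      first_center = first_center,
      spacing = spacing,
      half_width = half_width,
      shg_channel = as.integer(shg_channel),
      ratio_num_channel = as.integer(ratio_num_channel),
      tpef_max_channel = as.integer(tpef_max_channel)
    ),
    class = "spectral_channels"
  )
}

#' @export
print.spectral_channels <- function(x, ...) {
  cat(sprintf(
    "<spectral_channels> %d channels, %.1f-%.1f nm, spacing %.1f nm\n",
    x$n_channels, x$centers[1], x$centers[x$n_channels], x$spacing
  ))
  invisible(x)
}

#' @exportS3Method
as_tibble.spectral_channels <- function(x, ...) {
  tibble::tibble(
    channel = seq_len(x$n_channels),
    center_nm = x$centers,
    lower_nm = x$centers - x$half_width,
    upper_nm = x$centers + x$half_width
  )
}

#' Center wavelength of a spectral channel
#'
#' @param k 1-based channel index (vectorized).
#' @param channels A [spectral_channels()] map.
#' @return Center wavelength(s) in nm: `first_center + (k - 1) * spacing`.
#' @examples
#' channel_center(2)   # 460 nm, the SHG channel
#' channel_center(16)  # 635 nm
#' @export
channel_center <- function(k, channels = spectral_channels()) {
  k <- as.integer(k)
  if (any(k < 1L | k > channels$n_channels)) {
    stop(sprintf("channel index out of range 1..%d", channels$n_channels))
  }
  channels$centers[k]
}

#' Map a wavelength to an RGB color
#'
#' Continuous piecewise-linear approximation of the visible spectrum
#' (380-780 nm), after Bruton's classic mapping: five linear hue segments with
#' linear intensity attenuation below 420 nm and above 700 nm. Wavelengths
#' outside \[380, 780\] are clipped to the nearest endpoint. The exact display
#' palette used on any given instrument is a rendering choice; this map only
#' affects visualization, never statistics.
#'
#' @param lambda Wavelength(s) in nm.
#' @return A numeric matrix with one row per wavelength and columns r, g, b in
#'   \[0, 1\].
#' @export
wavelength_to_rgb <- function(lambda) {
  lambda <- pmin(pmax(as.numeric(lambda), 380), 780)
  r <- g <- b <- numeric(length(lambda))

  i <- lambda < 440
  r[i] <- (440 - lambda[i]) / (440 - 380); b[i] <- 1
  i <- lambda >= 440 & lambda < 490
  g[i] <- (lambda[i] - 440) / (490 - 440); b[i] <- 1
  i <- lambda >= 490 & lambda < 510
  g[i] <- 1; b[i] <- (510 - lambda[i]) / (510 - 490)
  i <- lambda >= 510 & lambda < 580
  r[i] <- (lambda[i] - 510) / (580 - 510); g[i] <- 1
  i <- lambda >= 580 & lambda < 645
  r[i] <- 1; g[i] <- (645 - lambda[i]) / (645 - 580)
  i <- lambda >= 645
  r[i] <- 1

  atten <- rep(1, length(lambda))
  i <- lambda < 420
  atten[i] <- 0.3 + 0.7 * (lambda[i] - 380) / (420 - 380)
  i <- lambda > 700
  atten[i] <- 0.3 + 0.7 * (780 - lambda[i]) / (780 - 700)

  cbind(r = r * atten, g = g * atten, b = b * atten)
}
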