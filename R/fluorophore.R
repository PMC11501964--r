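#' Fluorophore forward model
#'
#' A fluorophore (or SHG-like scatterer) is described by a Gaussian emission
#' profile sampled onto the spectral channel grid, a multi-exponential decay
#' given as amplitude fractions and lifetimes, and an expected photon budget
#' per pixel. Setting `emission_fwhm = 0` produces a spectral line confined to
#' the channel nearest the emission center, the model used for SHG (460 nm at
#' 920 nm excitation).
#'
#' @param name Species label.
#' @param emission_center Emission peak, in nm.
#' @param emission_fwhm Emission full width at half maximum, in nm; 0 for a
#'   single-channel line.
#' @param components Data frame (or tibble) with columns `fraction` (amplitude
#'   fractions summing to 1) and `lifetime_ns` (> 0).
#' @param brightness Expected photons per pixel contributed by this species.
#' @return An object of class `fluorophore`.
#' @examples
#' fad <- fluorophore("FAD", 522.5, 60,
#'                    data.frame(fraction = c(0.7, 0.3), lifetime_ns = c(0.5, 2.5)),
#'                    brightness = 3000)
#' @export
fluorophore <- function(name, emission_center, emission_fwhm, components,
                        brightness) {
  components <- tibble::as_tibble(components)
  stopifnot(all(c("fraction", "lifetime_ns") %in% names(components)))
  if (abs(sum(components$fraction) - 1) > 1e-9) {
    stop("amplitude fractions must sum to 1")
  }
  if (any(components$fraction < 0)) stop("amplitude fractions must be >= 0")
  if (any(components$lifetime_ns <= 0)) stop("lifetimes must be positive")
  if (emission_fwhm < 0) stop("emission fwhm must be nonnegative")
  if (brightness < 0) stop("brightness must be nonnegative")
  structure(
    list(name = name, emission_center = emission_center,
         emission_fwhm = emission_fwhm, components = components,
         brightness = brightness),
    class = "fluorophore"
  )
}

#' SHG-like species: a spectral line with an effectively instantaneous decay
#'
#' @param brightness Expected photons per pixel.
#' @param center Line position in nm (default 460, half the 920 nm excitation).
#' @return A [fluorophore()] with zero emission width and a 0.01 ns lifetime.
#' @export
shg_species <- function(brightness, center = 460) {
  fluorophore("SHG", center, 0,
              data.frame(fraction = 1, lifetime_ns = 0.01), brightness)
}

#' Normalized emission profile on the channel grid
#'
#' Samples the species' Gaussian emission at the channel centers and normalizes
#' to unit sum (so `brightness` is the total expected photon count across all
#' channels). A zero-width species puts all weight in the nearest channel.
#'
#' @param fluor A [fluorophore()].
#' @param channels A [spectral_channels()] map.
#' @return Nonnegative numeric vector of length `n_channels` summing to 1.
#' @export
emission_profile <- function(fluor, channels = spectral_channels()) {
  centers <- channels$centers
  if (fluor$emission_fwhm == 0) {
    p <- numeric(length(centers))
    p[which.min(abs(centers - fluor$emission_center))] <- 1
    return(p)
  }
  sigma <- fluor$emission_fwhm / (2 * sqrt(2 * log(2)))
  p <- exp(-(centers - fluor$emission_center)^2 / (2 * sigma^2))
  p / sum(p)
}

#' Normalized decay shape on the acquisition time grid
#'
#' Evaluates the species' multi-exponential decay at the bin centers,
#' convolves with the Gaussian IRF of the configuration (if its width is
#' positive), and normalizes to unit sum.
#'
#' @param fluor A [fluorophore()].
#' @param config An [acquisition_config()].
#' @param irf Optional kernel overriding the configuration's IRF; `NULL` uses
#'   `gaussian_irf(config$irf_fwhm, config)`.
#' @return Nonnegative numeric vector of length `n_time_bins` summing to 1.
#' @export
decay_shape <- function(fluor, config = acquisition_config(), irf = NULL) {
  t <- time_bin_centers(config)
  d <- rep(0, length(t))
  for (i in seq_len(nrow(fluor$components))) {
    tau <- fluor$components$lifetime_ns[i]
    if (tau >= config$time_window * 10) {
      warning(sprintf(
        "lifetime %.3g ns is unresolvable in a %.3g ns window", tau,
        config$time_window))
    }
    d <- d + fluor$components$fraction[i] * exp(-t / tau)
  }
  if (is.null(irf)) {
    if (config$irf_fwhm > 0) irf <- gaussian_irf(config$irf_fwhm, config)
  }
  if (!is.null(irf) && !(length(irf) == 1L && irf[1] == 1)) {
    d <- convolve_causal(d, irf)
  }
  d / sum(d)
}

# causal discrete convolution truncated to the length of x
convolve_causal <- function(x, kernel) {
  n <- length(x)
  out <- stats::convolve(c(x, numeric(length(kernel))), rev(kernel),
                         type = "open")
  out <- out[seq_len(n)]
  out[out < 0] <- 0   # clip FFT round-off
  out
}
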