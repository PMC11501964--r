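#' RGB spectral encoding of a multichannel stack
#'
#' Each channel's grayscale image is multiplied by the RGB color of its center
#' wavelength and the 16 color images are summed; the result is normalized to
#' \[0, 1\] by the frame maximum, so the encoding is invariant to a global
#' intensity rescaling. An all-zero stack encodes to black.
#'
#' @param stack H x W x omega array of nonnegative channel counts.
#' @param channels A [spectral_channels()] map matching the stack's third
#'   dimension.
#' @return An H x W x 3 array with values in \[0, 1\].
#' @export
spectral_encode <- function(stack, channels = spectral_channels()) {
  stack <- check_stack(stack, channels$n_channels)
  cols <- wavelength_to_rgb(channels$centers)
  d <- dim(stack)
  flat <- matrix(stack, ncol = d[3])          # pixels x channels
  rgb <- flat %*% cols                        # pixels x 3
  m <- max(rgb)
  if (m > 0) rgb <- rgb / m
  array(rgb, dim = c(d[1], d[2], 3L))
}

#' Integrated emission spectrum of a region
#'
#' Sums the per-channel counts over the pixels selected by a mask, yielding the
#' region's spectral curve.
#'
#' @param stack H x W x omega array of channel counts.
#' @param mask H x W logical matrix; must select at least one pixel.
#' @param channels A [spectral_channels()] map.
#' @return A tibble with columns `channel`, `center_nm`, `counts`.
#' @export
extract_region_spectrum <- function(stack, mask, channels = spectral_channels()) {
  stack <- check_stack(stack, channels$n_channels)
  if (!is.logical(mask) || !identical(dim(mask), dim(stack)[1:2])) {
    stop("mask must be a logical matrix congruent with the stack")
  }
  if (!any(mask)) stop("region mask selects no pixels")
  counts <- vapply(seq_len(dim(stack)[3]),
                   function(k) sum(stack[, , k][mask]), numeric(1))
  tibble::tibble(
    channel = seq_along(counts),
    center_nm = channels$centers,
    counts = counts
  )
}

spectrum_counts <- function(spectrum, channels) {
  if (is.data.frame(spectrum)) {
    counts <- spectrum$counts
  } else {
    counts <- as.numeric(spectrum)
  }
  if (length(counts) != channels$n_channels) {
    stop("spectrum length does not match the channel map")
  }
  counts
}

channel_ratio <- function(spectrum, num_ch, den_ch, channels) {
  counts <- spectrum_counts(spectrum, channels)
  den <- counts[den_ch]
  if (den <= 0) {
    warning(sprintf("denominator channel %d has zero counts; ratio undefined",
                    den_ch))
    return(NA_real_)
  }
  counts[num_ch] / den
}

#' SHG/TPEF ratio of a region spectrum
#'
#' Divides the SHG signal (channel 2, 460 +/- 6.25 nm) by the maximum TPEF
#' channel (channel 7, 522.5 +/- 6.25 nm). The ratio quantifies collagen
#' content relative to cellular autofluorescence and is invariant under global
#' intensity scaling. A zero denominator yields `NA` with a warning so the
#' value is excluded from group statistics rather than becoming an infinity.
#'
#' @param spectrum A tibble from [extract_region_spectrum()] or a bare
#'   omega-vector of channel counts.
#' @param channels A [spectral_channels()] map.
#' @return A unitless scalar (or `NA` if undefined).
#' @export
shg_tpef_ratio <- function(spectrum, channels = spectral_channels()) {
  channel_ratio(spectrum, channels$shg_channel, channels$tpef_max_channel,
                channels)
}

#' TPEF spectral ratio of a region spectrum
#'
#' Divides the short-wavelength TPEF band (channel 4, 485 +/- 6.25 nm) by the
#' maximum TPEF channel (channel 7, 522.5 +/- 6.25 nm). The ratio tracks the
#' blue shift of the autofluorescence spectrum associated with altered cellular
#' metabolism.
#'
#' @inheritParams shg_tpef_ratio
#' @return A unitless scalar (or `NA` if undefined).
#' @export
tpef_spectral_ratio <- function(spectrum, channels = spectral_channels()) {
  channel_ratio(spectrum, channels$ratio_num_channel, channels$tpef_max_channel,
                channels)
}

check_stack <- function(stack, n_channels = NULL) {
  if (!is.array(stack) || length(dim(stack)) != 3L) {
    stop("stack must be an H x W x channels array")
  }
  if (!is.null(n_channels) && dim(stack)[3] != n_channels) {
    stop(sprintf("stack has %d channels but the channel map declares %d",
                 dim(stack)[3], n_channels))
  }
  if (any(stack < 0)) stop("stack counts must be nonnegative")
  stack
}
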