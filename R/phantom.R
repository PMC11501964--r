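#' Default per-class fluorophore models for the skin phantom
#'
#' Each tissue class mixes a TPEF species (a FAD-dominated Gaussian emitter
#' with a two-component decay) and, where collagen is present, an SHG line at
#' 460 nm. The classes are constructed to carry the qualitative contrasts seen
#' between healthy skin and basal cell carcinoma regions:
#' \itemize{
#'   \item mean lifetime: NORMAL shortest; among lesion classes NEIR is shorter
#'     than NOIR and IR;
#'   \item short/long amplitude ratio a1/a2: NORMAL highest, NEIR above IR;
#'   \item TPEF spectral ratio (Ch4/Ch7): decreasing NORMAL > NOIR > NEIR > IR
#'     (the emission center red-shifts with invasion);
#'   \item SHG/TPEF: equal in expectation for NORMAL and NOIR (collagen intact
#'     outside the tumor; the NOIR collagen brightness is solved numerically so
#'     the two expected ratios coincide), collapsing in NEIR and almost absent
#'     in IR.
#' }
#' BACKGROUND renders zero expected signal.
#'
#' @param channels A [spectral_channels()] map used to solve the NOIR collagen
#'   brightness.
#' @param tpef_brightness Expected TPEF photons per pixel (default 3000).
#' @return Named list mapping class name to a list of
#'   `list(species = fluorophore, weight = numeric)` entries.
#' @export
default_class_models <- function(channels = spectral_channels(),
                                 tpef_brightness = 3000) {
  tpef <- function(center, a1, brightness = tpef_brightness) {
    fluorophore(sprintf("TPEF-%g", center), center, 60,
                data.frame(fraction = c(a1, 1 - a1),
                           lifetime_ns = c(0.5, 2.5)),
                brightness)
  }
  normal_tpef <- tpef(505, 0.80)
  noir_tpef <- tpef(512, 0.45)

  # solve NOIR collagen brightness so E[Ch2/Ch7] matches NORMAL exactly
  shg_ch <- channels$shg_channel
  max_ch <- channels$tpef_max_channel
  p_n <- emission_profile(normal_tpef, channels) * normal_tpef$brightness
  shg_normal <- 1000
  ratio_normal <- (p_n[shg_ch] + shg_normal) / p_n[max_ch]
  p_o <- emission_profile(noir_tpef, channels) * noir_tpef$brightness
  shg_noir <- ratio_normal * p_o[max_ch] - p_o[shg_ch]

  entry <- function(species, weight = 1) list(species = species, weight = weight)
  list(
    BACKGROUND = list(),
    NORMAL = list(entry(normal_tpef), entry(shg_species(shg_normal))),
    EPIDERMIS = list(entry(tpef(500, 0.75, tpef_brightness * 1.2))),
    DERMIS = list(entry(normal_tpef), entry(shg_species(shg_normal))),
    NOIR = list(entry(noir_tpef), entry(shg_species(shg_noir))),
    NEIR = list(entry(tpef(518, 0.55)), entry(shg_species(300))),
    IR = list(entry(tpef(526, 0.30)), entry(shg_species(30)))
  )
}

phantom_layout <- function(layout, dim, classes = NULL) {
  h <- dim[1]; w <- dim[2]
  if (is.matrix(layout)) return(layout)
  row_f <- matrix(rep((seq_len(h) - 0.5) / h, w), h, w)
  col_f <- matrix(rep((seq_len(w) - 0.5) / w, each = h), h, w)
  rn <- sqrt(((row_f - 0.5) * 2)^2 + ((col_f - 0.5) * 2)^2)
  lab <- matrix(NA_character_, h, w)
  switch(layout,
    two_band = {
      cl <- classes %||% c("NORMAL", "IR")
      lab[row_f <= 0.5] <- cl[1]
      lab[row_f > 0.5] <- cl[2]
    },
    three_ring = {
      lab[] <- "NOIR"
      lab[rn < 0.75] <- "NEIR"
      lab[rn < 0.40] <- "IR"
    },
    four_quadrant = {
      cl <- classes %||% c("NORMAL", "NOIR", "NEIR", "IR")
      lab[row_f <= 0.5 & col_f <= 0.5] <- cl[1]
      lab[row_f <= 0.5 & col_f > 0.5] <- cl[2]
      lab[row_f > 0.5 & col_f <= 0.5] <- cl[3]
      lab[row_f > 0.5 & col_f > 0.5] <- cl[4]
    },
    bcc = {
      lab[] <- "DERMIS"
      lab[row_f < 0.15] <- "EPIDERMIS"
      rt <- sqrt(((row_f - 0.60) * 2)^2 + ((col_f - 0.5) * 2)^2)
      lab[rt < 0.55] <- "NOIR"
      lab[rt < 0.38] <- "NEIR"
      lab[rt < 0.22] <- "IR"
    },
    stop(sprintf("unknown layout preset '%s'", layout))
  )
  lab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a tissue phantom with known ground truth
#'
#' A phantom is an integer label map over a pixel grid plus per-class
#' fluorophore models; it is the synthetic stand-in for a sectioned tissue
#' sample and carries the ground truth against which every downstream stage is
#' validated. Geometry is deterministic; the seed is stored and drives all
#' photon noise in the render functions.
#'
#' Presets: `"two_band"` (horizontal halves), `"three_ring"` (IR core, NEIR
#' ring, NOIR surround), `"four_quadrant"`, `"bcc"` (epidermis band over
#' dermis with nested NOIR/NEIR/IR tumor lobe). An explicit character matrix
#' of class names can be given instead.
#'
#' @param layout Preset name or H x W character matrix of class names.
#' @param dim Image size `c(H, W)` when a preset is used.
#' @param class_models Per-class species lists, as [default_class_models()].
#' @param pixel_size Pixel pitch in micrometers.
#' @param seed Integer seed driving all subsequent photon noise.
#' @param classes Optional class names for presets that accept them.
#' @return An object of class `tissue_phantom` with `label_map` (integer
#'   matrix), `legend` (id -> name), `class_models`, `pixel_size`, `seed`.
#' @export
make_phantom <- function(layout = "bcc", dim = c(64L, 64L),
                         class_models = default_class_models(),
                         pixel_size = 0.62, seed = 1L, classes = NULL) {
  lab <- phantom_layout(layout, dim, classes)
  used <- sort(unique(as.vector(lab)))
  unknown <- setdiff(used, names(class_models))
  if (length(unknown) > 0) {
    stop(sprintf("layout uses classes with no model: %s",
                 paste(unknown, collapse = ", ")))
  }
  legend <- stats::setNames(seq_along(used), used)
  label_map <- matrix(legend[lab], nrow(lab), ncol(lab))
  structure(
    list(label_map = label_map, legend = legend,
         class_models = class_models[used], pixel_size = pixel_size,
         seed = as.integer(seed)),
    class = "tissue_phantom"
  )
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf("<tissue_phantom> %d x %d px, classes: %s (seed %d)\n",
              nrow(x$label_map), ncol(x$label_map),
              paste(names(x$legend), collapse = ", "), x$seed))
  invisible(x)
}

#' Per-pixel class fractions of a phantom
#'
#' @param phantom A [make_phantom()] object.
#' @return Tibble with `class`, `n_pixels`, `fraction`.
#' @export
phantom_class_counts <- function(phantom) {
  tab <- table(factor(phantom$label_map, levels = phantom$legend,
                      labels = names(phantom$legend)))
  tibble::tibble(class = names(tab), n_pixels = as.integer(tab),
                 fraction = as.integer(tab) / length(phantom$label_map))
}

#' Expected emission spectrum of a phantom class
#'
#' Sum over the class's species of weight x brightness x normalized emission
#' profile: the Poisson mean of a single pixel's channel vector.
#'
#' @param phantom A [make_phantom()] object.
#' @param class Class name.
#' @param config An [acquisition_config()].
#' @return Numeric vector of expected counts per channel.
#' @export
class_expected_spectrum <- function(phantom, class,
                                    config = acquisition_config()) {
  entries <- phantom$class_models[[class]]
  mu <- rep(0, config$channels$n_channels)
  for (e in entries) {
    mu <- mu + e$weight * e$species$brightness *
      emission_profile(e$species, config$channels)
  }
  mu
}

#' Expected decay histogram of a phantom class
#'
#' @inheritParams class_expected_spectrum
#' @param channel Optional 1-based spectral channel: when given, each species
#'   contributes brightness x its emission share in that channel (the photons
#'   actually detected there); when `NULL`, the full brightness.
#' @param irf Optional IRF kernel overriding the configuration's.
#' @return Numeric vector of expected counts per time bin.
#' @export
class_expected_decay <- function(phantom, class,
                                 config = acquisition_config(),
                                 channel = NULL, irf = NULL) {
  entries <- phantom$class_models[[class]]
  mu <- rep(0, config$n_time_bins)
  for (e in entries) {
    budget <- e$weight * e$species$brightness
    if (!is.null(channel)) {
      budget <- budget * emission_profile(e$species, config$channels)[channel]
    }
    if (budget == 0) next
    mu <- mu + budget * decay_shape(e$species, config, irf = irf)
  }
  mu
}

render_by_class <- function(phantom, per_class_mu, n_out, seed, noise) {
  h <- nrow(phantom$label_map); w <- ncol(phantom$label_map)
  out <- array(0, dim = c(h, w, n_out))
  withr::with_seed(seed, {
    for (class in names(phantom$legend)) {
      idx <- which(phantom$label_map == phantom$legend[[class]])
      if (length(idx) == 0) next
      mu <- per_class_mu[[class]]
      for (k in seq_len(n_out)) {
        plane <- out[, , k]
        plane[idx] <- if (noise) stats::rpois(length(idx), mu[k]) else mu[k]
        out[, , k] <- plane
      }
    }
  })
  out
}

#' Render a noisy spectral stack from a phantom
#'
#' Each pixel's channel vector is an independent Poisson draw around the
#' expected spectrum of its class. Deterministic for a fixed seed.
#'
#' @param phantom A [make_phantom()] object.
#' @param config An [acquisition_config()].
#' @param seed Integer seed; defaults to the phantom's.
#' @param noise If `FALSE`, return the noiseless expectation.
#' @return H x W x n_channels array of counts.
#' @export
render_spectral_stack <- function(phantom, config = acquisition_config(),
                                  seed = phantom$seed, noise = TRUE) {
  mus <- lapply(stats::setNames(nm = names(phantom$legend)),
                function(cl) class_expected_spectrum(phantom, cl, config))
  render_by_class(phantom, mus, config$channels$n_channels, seed, noise)
}

#' Render a noisy TCSPC decay stack from a phantom
#'
#' Each pixel's time histogram is an independent Poisson draw around its
#' class's IRF-convolved multi-exponential expectation. With `channel = NULL`
#' the total expected photons per pixel equal the summed species brightness.
#'
#' @inheritParams render_spectral_stack
#' @inheritParams class_expected_decay
#' @return An object of class `decay_stack`: list with `counts`
#'   (H x W x n_time_bins array), `bin_width` (ns), `t0`, `config`.
#' @export
render_decay_stack <- function(phantom, config = acquisition_config(),
                               seed = phantom$seed, noise = TRUE,
                               channel = NULL, irf = NULL) {
  mus <- lapply(stats::setNames(nm = names(phantom$legend)), function(cl) {
    class_expected_decay(phantom, cl, config, channel = channel, irf = irf)
  })
  counts <- render_by_class(phantom, mus, config$n_time_bins, seed + 1L, noise)
  structure(list(counts = counts, bin_width = config$bin_width, t0 = 0,
                 config = config),
            class = "decay_stack")
}

#' @export
print.decay_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<decay_stack> %d x %d px, %d bins of %.4f ns\n",
              d[1], d[2], d[3], x$bin_width))
  invisible(x)
}
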