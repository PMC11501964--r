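#' Biexponential fluorescence decay model
#'
#' Evaluates `I0 * (a1 * exp(-t / tau1) + a2 * exp(-t / tau2))`, the standard
#' two-component model for autofluorescence decays in which a short-lifetime
#' component (free fluorophore) and a long-lifetime component (protein-bound
#' fluorophore) mix.
#'
#' @param t Time grid in ns.
#' @param I0 Intensity scale at t = 0 (for `a1 + a2 = 1`).
#' @param a1,a2 Nonnegative component amplitudes.
#' @param tau1,tau2 Component lifetimes in ns (> 0).
#' @return Numeric vector of model intensities.
#' @export
biexp_model <- function(t, I0, a1, tau1, a2, tau2) {
  if (tau1 <= 0 || tau2 <= 0) stop("lifetimes must be positive")
  I0 * (a1 * exp(-t / tau1) + a2 * exp(-t / tau2))
}

#' Amplitude-weighted mean lifetime
#'
#' `tau_mean = (a1 * tau1 + a2 * tau2) / (a1 + a2)`, the per-pixel summary
#' used as the metabolic-state readout; it is invariant to rescaling both
#' amplitudes and always lies between the two component lifetimes.
#'
#' @inheritParams biexp_model
#' @return Mean lifetime in ns.
#' @export
tau_mean <- function(a1, tau1, a2, tau2) {
  if (any(a1 + a2 <= 0)) stop("a1 + a2 must be positive")
  (a1 * tau1 + a2 * tau2) / (a1 + a2)
}

# model expectation over the full bin grid, optionally IRF-convolved
biexp_expected <- function(t, A, a, tau1, tau2, irf = NULL) {
  shape <- a * exp(-t / tau1) + (1 - a) * exp(-t / tau2)
  if (!is.null(irf)) shape <- convolve_causal(shape, irf)
  A * shape
}

#' Fit a biexponential model to a TCSPC histogram
#'
#' Weighted least squares with Poisson weights `1 / max(counts, 1)`, solved by
#' Levenberg-Marquardt over the transformed parameters (log scale, logit
#' amplitude fraction, log lifetimes) so positivity is structural. When an IRF
#' kernel is supplied the model is the IRF-convolved biexponential over the
#' full time grid; otherwise a tail fit is performed from the histogram peak
#' onward with time re-zeroed at the peak. The returned parameters are
#' canonicalized so `tau1 <= tau2`; amplitudes are reported as fractions with
#' `a1 + a2 = 1`.
#'
#' Initialization (overridable via `init`): `tau2` from a log-linear fit to
#' the tail, `tau1 = tau2 / 5`, equal amplitudes, scale from the peak count.
#'
#' @param counts Nonnegative T-vector of photon counts.
#' @param config An [acquisition_config()] supplying the time grid, or pass
#'   `times` directly.
#' @param times Optional explicit bin-center grid in ns.
#' @param irf Optional IRF kernel (as [gaussian_irf()]).
#' @param min_photons Minimum total photons required (default 100); below it a
#'   `phasorflim_not_enough_photons` error is raised.
#' @param init Optional named list overriding `tau1`, `tau2`, `a1`, `I0`.
#' @return An object of class `decay_fit` with fields `a1`, `a2`, `tau1`,
#'   `tau2`, `I0`, `tau_mean`, `chi2_reduced`, `n_photons`, `converged`.
#' @export
fit_decay <- function(counts, config = acquisition_config(), times = NULL,
                      irf = NULL, min_photons = 100, init = NULL) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  n_photons <- sum(counts)
  if (n_photons < min_photons) {
    rlang::abort(
      sprintf("histogram has %g photons, below min_photons = %g",
              n_photons, min_photons),
      class = "phasorflim_not_enough_photons"
    )
  }
  if (is.null(times)) times <- time_bin_centers(config)
  if (length(times) != length(counts)) stop("times/counts length mismatch")

  if (is.null(irf)) {
    # peak located on a 3-bin moving average so a single noisy bin cannot
    # shift the fit origin and discard true early-decay data
    n <- length(counts)
    smoothed <- vapply(seq_len(n), function(i) {
      mean(counts[max(1, i - 1):min(n, i + 1)])
    }, numeric(1))
    peak <- which.max(smoothed)
    t_offset <- times[peak]
    t <- times[peak:length(times)] - t_offset
    y <- counts[peak:length(counts)]
  } else {
    t_offset <- 0
    t <- times
    y <- counts
  }
  w <- 1 / pmax(y, 1)

  ini <- fit_decay_init(t, y, init)
  # lifetimes are constrained to [one bin width, 4 x window]: components
  # faster than the sampling are indistinguishable from one-bin spikes that
  # absorb single-bin noise, and slower ones are flat within the window
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  tau_lo <- dt
  tau_hi <- 4 * (max(times) - min(times) + dt)
  from_ltau <- function(ltau) {
    tau_lo + (tau_hi - tau_lo) * stats::plogis(ltau)
  }
  to_ltau <- function(tau) {
    stats::qlogis(min(max((tau - tau_lo) / (tau_hi - tau_lo), 1e-3), 1 - 1e-3))
  }
  residual <- function(par) {
    m <- biexp_expected(t, exp(par[["logA"]]), stats::plogis(par[["qa"]]),
                        from_ltau(par[["ltau1"]]), from_ltau(par[["ltau2"]]),
                        irf = irf)
    (y - m) * sqrt(w)
  }
  # the weighted least-squares surface can hold several minima; start from
  # a few amplitude / lifetime splits and keep the best optimum
  starts <- list(
    c(a1 = ini$a1, tau1 = ini$tau1, tau2 = ini$tau2),
    c(a1 = 0.8, tau1 = ini$tau2 / 3, tau2 = ini$tau2),
    c(a1 = 0.15, tau1 = ini$tau2 / 3, tau2 = ini$tau2),
    c(a1 = 0.5, tau1 = ini$tau2 * 0.9, tau2 = ini$tau2 * 1.1)
  )
  if (!is.null(init)) starts <- starts[1]
  fit <- NULL
  for (s in starts) {
    par0 <- c(logA = log(ini$I0), qa = stats::qlogis(s[["a1"]]),
              ltau1 = to_ltau(s[["tau1"]]), ltau2 = to_ltau(s[["tau2"]]))
    cand <- minpack.lm::nls.lm(par0, fn = residual,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200, ptol = 1e-12, ftol = 1e-12))
    if (is.null(fit) || sum(cand$fvec^2) < sum(fit$fvec^2)) fit <- cand
  }
  p <- fit$par
  tau1 <- from_ltau(p[["ltau1"]]); tau2 <- from_ltau(p[["ltau2"]])
  # refer amplitudes back to the histogram time origin (tail fits re-zero
  # time at the peak, which deflates the fast component's share); a
  # component pinned at the resolution floor is an unresolvable spike and
  # gets no origin correction
  corr <- function(tau) if (tau > 1.5 * tau_lo) exp(t_offset / tau) else 1
  b1 <- stats::plogis(p[["qa"]]) * exp(p[["logA"]]) * corr(tau1)
  b2 <- (1 - stats::plogis(p[["qa"]])) * exp(p[["logA"]]) * corr(tau2)
  I0 <- b1 + b2
  a1 <- b1 / I0; a2 <- b2 / I0
  if (tau1 > tau2) {           # canonical ordering, swap-symmetric
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    tmp <- a1; a1 <- a2; a2 <- tmp
  }
  dof <- max(length(y) - 4L, 1L)
  structure(
    list(a1 = a1, a2 = a2, tau1 = tau1, tau2 = tau2, I0 = I0,
         tau_mean = tau_mean(a1, tau1, a2, tau2),
         chi2_reduced = sum(fit$fvec^2) / dof,
         n_photons = n_photons,
         converged = fit$info %in% 1:3),
    class = "decay_fit"
  )
}

fit_decay_init <- function(t, y, init) {
  pos <- which(y > 0)
  tail_idx <- pos[pos >= stats::quantile(pos, 0.5)]
  tau2 <- 2
  if (length(tail_idx) >= 3) {
    sl <- stats::coef(stats::lm(log(y[tail_idx]) ~ t[tail_idx]))[2]
    if (is.finite(sl) && sl < 0) tau2 <- min(max(-1 / sl, 0.05), 50)
  }
  ini <- list(tau1 = tau2 / 5, tau2 = tau2, a1 = 0.5, I0 = max(y))
  if (!is.null(init)) ini[names(init)] <- init
  ini
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> tau1 %.3f ns (a1 %.3f), tau2 %.3f ns (a2 %.3f), tau_mean %.3f ns, chi2_red %.3g%s\n",
    x$tau1, x$a1, x$tau2, x$a2, x$tau_mean, x$chi2_reduced,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @exportS3Method
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a1", "a2", "tau1", "tau2", "tau_mean", "I0"),
    estimate = c(x$a1, x$a2, x$tau1, x$tau2, x$tau_mean, x$I0)
  )
}

#' @exportS3Method
glance.decay_fit <- function(x, ...) {
  tibble::tibble(tau_mean = x$tau_mean, amplitude_ratio = x$a1 / x$a2,
                 chi2_reduced = x$chi2_reduced, n_photons = x$n_photons,
                 converged = x$converged)
}

box_neighborhood_sum <- function(stack_counts, radius) {
  if (radius == 0) return(stack_counts)
  d <- dim(stack_counts)
  out <- array(0, dim = d)
  for (di in -radius:radius) {
    ri <- pmin(pmax(seq_len(d[1]) + di, 1L), d[1])
    for (dj in -radius:radius) {
      cj <- pmin(pmax(seq_len(d[2]) + dj, 1L), d[2])
      out <- out + stack_counts[ri, cj, , drop = FALSE]
    }
  }
  out
}

#' Per-pixel biexponential fitting of a decay stack
#'
#' Fits every pixel of a [render_decay_stack()] (or equivalent) stack. With
#' `binning = r` the histogram fitted at each pixel is the sum over its
#' (2r+1) x (2r+1) neighborhood (edge-replicated), the usual TCSPC practice
#' for raising per-pixel photon counts; `binning = 0` fits each pixel's own
#' histogram. Pixels whose (binned) histograms hold fewer than `min_photons`
#' photons are masked `NA`.
#'
#' @param stack A `decay_stack` object.
#' @param binning Neighborhood radius in pixels (default 1, i.e. 3 x 3).
#' @param irf,min_photons,init Passed to [fit_decay()].
#' @return An object of class `flim_image`: matrices `tau_mean`, `tau1`,
#'   `tau2`, `a1`, `a2`, `amplitude_ratio`, `chi2_reduced`, `n_photons`,
#'   logical `converged` and `fitted_mask`.
#' @export
fit_image <- function(stack, binning = 1L, irf = NULL, min_photons = 100,
                      init = NULL) {
  stopifnot(inherits(stack, "decay_stack"), binning >= 0)
  counts <- box_neighborhood_sum(stack$counts, as.integer(binning))
  d <- dim(counts)
  times <- (seq_len(d[3]) - 0.5) * stack$bin_width + stack$t0
  maps <- c("tau_mean", "tau1", "tau2", "a1", "a2", "amplitude_ratio",
            "chi2_reduced")
  out <- stats::setNames(
    replicate(length(maps), matrix(NA_real_, d[1], d[2]), simplify = FALSE),
    maps)
  out$n_photons <- matrix(rowSums(matrix(counts, ncol = d[3])), d[1], d[2])
  out$converged <- matrix(FALSE, d[1], d[2])
  out$fitted_mask <- out$n_photons >= min_photons
  for (j in seq_len(d[2])) {
    for (i in seq_len(d[1])) {
      if (!out$fitted_mask[i, j]) next
      f <- fit_decay(counts[i, j, ], times = times, irf = irf,
                     min_photons = min_photons, init = init)
      out$tau_mean[i, j] <- f$tau_mean
      out$tau1[i, j] <- f$tau1; out$tau2[i, j] <- f$tau2
      out$a1[i, j] <- f$a1; out$a2[i, j] <- f$a2
      out$amplitude_ratio[i, j] <- f$a1 / f$a2
      out$chi2_reduced[i, j] <- f$chi2_reduced
      out$converged[i, j] <- f$converged
    }
  }
  structure(c(out, list(binning = as.integer(binning))), class = "flim_image")
}

#' @export
print.flim_image <- function(x, ...) {
  cat(sprintf(
    "<flim_image> %d x %d px, %d fitted, median tau_mean %.3f ns (binning %d)\n",
    nrow(x$tau_mean), ncol(x$tau_mean), sum(x$fitted_mask),
    stats::median(x$tau_mean, na.rm = TRUE), x$binning))
  invisible(x)
}

#' @exportS3Method
tidy.flim_image <- function(x, ...) {
  d <- dim(x$tau_mean)
  tibble::tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    tau_mean = as.vector(x$tau_mean),
    tau1 = as.vector(x$tau1), tau2 = as.vector(x$tau2),
    a1 = as.vector(x$a1), a2 = as.vector(x$a2),
    amplitude_ratio = as.vector(x$amplitude_ratio),
    chi2_reduced = as.vector(x$chi2_reduced),
    n_photons = as.vector(x$n_photons),
    converged = as.vector(x$converged)
  )
}

#' Lifetime-coded RGB image
#'
#' Encodes a mean-lifetime map as hue and photon intensity as value: hue runs
#' linearly from blue (HSV hue 2/3) at the lower display limit to red (hue 0)
#' at the upper limit — the conventional short-to-long rainbow reversed so
#' long lifetimes appear warm is *not* used; the map is documented as
#' blue = short, red = long. Lifetimes are clipped to the range; pixels with
#' `NA` lifetime or zero intensity are black.
#'
#' @param tau_map H x W matrix of mean lifetimes (ns).
#' @param intensity_map H x W nonnegative matrix (photon counts).
#' @param range Display limits `c(min, max)` in ns.
#' @return H x W x 3 array in \[0, 1\].
#' @export
lifetime_coded_image <- function(tau_map, intensity_map,
                                 range = c(0.5, 2.5)) {
  if (range[1] >= range[2]) stop("display range must have min < max")
  stopifnot(identical(dim(tau_map), dim(intensity_map)))
  frac <- (pmin(pmax(tau_map, range[1]), range[2]) - range[1]) /
    (range[2] - range[1])
  hue <- (1 - frac) * (2 / 3)                 # blue (short) -> red (long)
  value <- intensity_map / max(intensity_map, 1e-300)
  ok <- !is.na(frac) & value > 0
  out <- array(0, dim = c(nrow(tau_map), ncol(tau_map), 3L))
  if (any(ok)) {
    rgb <- grDevices::col2rgb(grDevices::hsv(hue[ok], 1, value[ok])) / 255
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[ok] <- rgb[ch, ]
      out[, , ch] <- plane
    }
  }
  out
}
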