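test_that("biexp_model evaluates the two-component decay exactly", {
  expect_equal(biexp_model(0, 120, 0.6, 0.5, 0.4, 2.5), 120)
  expect_equal(biexp_model(0.5, 7, 1, 0.5, 0, 2.5), 7 / exp(1))
  expect_equal(biexp_model(1, 100, 0.75, 0.5, 0.25, 2.5),
               100 * (0.75 * exp(-2) + 0.25 * exp(-0.4)))
  t <- seq(0, 10, by = 0.1)
  expect_true(all(diff(biexp_model(t, 10, 0.5, 0.4, 0.5, 3)) < 0))
  expect_error(biexp_model(1, 1, 1, -0.5, 0, 1), "positive")
})

test_that("tau_mean identities hold exactly and rescaling amplitudes is neutral", {
  expect_equal(tau_mean(1, 0.5, 1, 2.5), 1.5)
  expect_equal(tau_mean(0.3, 1.7, 0, 2.5), 1.7)
  expect_equal(tau_mean(3, 0.5, 1, 2.5), 1.0)
  expect_equal(tau_mean(0.2, 0.5, 0.6, 2.5), tau_mean(2, 0.5, 6, 2.5))
  for (i in 1:10) {
    a1 <- runif(1); a2 <- runif(1); t1 <- runif(1, 0.1, 1); t2 <- runif(1, 1, 4)
    tm <- tau_mean(a1, t1, a2, t2)
    expect_gte(tm, t1); expect_lte(tm, t2)
  }
  expect_error(tau_mean(0, 1, 0, 2), "positive")
})

test_that("noiseless biexponential fits recover all parameters to 1e-3 relative", {
  acq <- acquisition_config(n_time_bins = 256)
  t <- time_bin_centers(acq)
  cases <- list(c(0.5, 0.5, 2.5), c(0.75, 0.5, 2.5), c(0.3, 0.8, 3.5))
  for (cs in cases) {
    y <- biexp_model(t, 1e4, cs[1], cs[2], 1 - cs[1], cs[3])
    f <- fit_decay(y, acq)
    expect_true(f$converged)
    expect_lt(abs(f$a1 - cs[1]) / cs[1], 1e-3)
    expect_lt(abs(f$tau1 - cs[2]) / cs[2], 1e-3)
    expect_lt(abs(f$tau2 - cs[3]) / cs[3], 1e-3)
    expect_lt(abs(f$I0 - 1e4) / 1e4, 1e-3)
    expect_lt(max(abs(biexp_model(t, f$I0, f$a1, f$tau1, f$a2, f$tau2) - y)),
              1e-6 * max(y))
  }
})

test_that("canonical ordering never alters the modeled curve", {
  acq <- acquisition_config(n_time_bins = 128)
  t <- time_bin_centers(acq)
  y <- biexp_model(t, 5e3, 0.25, 2.5, 0.75, 0.5)  # deliberately swapped input
  f <- fit_decay(y, acq)
  expect_lte(f$tau1, f$tau2)
  expect_equal(biexp_model(t, f$I0, f$a1, f$tau1, f$a2, f$tau2), y,
               tolerance = 1e-6)
})

test_that("monoexponential input yields tau_mean within 2% whatever the split", {
  acq <- acquisition_config(n_time_bins = 256)
  t <- time_bin_centers(acq)
  for (tau in c(0.8, 1.5, 2.5)) {
    f <- fit_decay(biexp_model(t, 2e4, 1, tau, 0, 1), acq)
    expect_lt(abs(f$tau_mean - tau) / tau, 0.02)
  }
  set.seed(77)
  mu <- biexp_model(t, 1, 1, 1.5, 0, 1); mu <- mu / sum(mu) * 1e5
  f <- fit_decay(rpois(length(mu), mu), acq)
  expect_lt(abs(f$tau_mean - 1.5) / 1.5, 0.02)
})

test_that("histograms below the photon floor raise NOT_ENOUGH_PHOTONS", {
  acq <- acquisition_config(n_time_bins = 64)
  expect_error(fit_decay(rep(1, 64), acq, min_photons = 100),
               class = "phasorflim_not_enough_photons")
})

test_that("tau_mean RMSE decreases with photon count", {
  acq <- acquisition_config(n_time_bins = 128)
  t <- time_bin_centers(acq)
  shape <- biexp_model(t, 1, 0.5, 0.5, 0.5, 2.5)
  shape <- shape / sum(shape)
  rmse <- vapply(c(1e3, 1e4, 1e5), function(n) {
    set.seed(101)
    errs <- replicate(30, {
      f <- fit_decay(rpois(length(shape), shape * n), acq)
      f$tau_mean - 1.5
    })
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("fit_image with binning 0 equals independent per-pixel fits", {
  models <- list(B = list(list(
    species = fluorophore("b", 520, 60,
                          data.frame(fraction = c(0.5, 0.5),
                                     lifetime_ns = c(0.5, 2.5)),
                          brightness = 2e4), weight = 1)))
  ph <- uniform_phantom("B", dim = c(4L, 4L), models = models, seed = 31)
  acq <- acquisition_config(n_time_bins = 128, irf_fwhm = 0)
  dec <- render_decay_stack(ph, acq)
  fi <- fit_image(dec, binning = 0)
  for (i in 1:4) {
    for (j in 1:4) {
      f <- fit_decay(dec$counts[i, j, ], acq)
      expect_equal(fi$tau_mean[i, j], f$tau_mean)
      expect_equal(fi$a1[i, j], f$a1)
    }
  }
})

test_that("a uniform phantom yields a spatially homogeneous tau_mean map", {
  models <- list(B = list(list(
    species = fluorophore("b", 520, 60,
                          data.frame(fraction = c(0.5, 0.5),
                                     lifetime_ns = c(0.5, 2.5)),
                          brightness = 1e4), weight = 1)))
  ph <- uniform_phantom("B", dim = c(10L, 10L), models = models, seed = 41)
  acq <- acquisition_config(n_time_bins = 128, irf_fwhm = 0)
  fi <- fit_image(render_decay_stack(ph, acq), binning = 0)
  cv <- sd(fi$tau_mean) / mean(fi$tau_mean)
  expect_lt(cv, 0.05)
  expect_true(all(fi$fitted_mask))
})

test_that("two-region phantom lifetimes are recovered with both regions within 5%", {
  mk <- function(a1) {
    list(list(species = fluorophore("f", 520, 60,
                                    data.frame(fraction = c(a1, 1 - a1),
                                               lifetime_ns = c(0.5, 2.5)),
                                    brightness = 1e4), weight = 1))
  }
  models <- list(SHORT = mk(0.75), LONG = mk(0.25))   # tau_mean 1.0 and 2.0
  ph <- make_phantom("two_band", dim = c(10L, 10L), class_models = models,
                     seed = 51, classes = c("SHORT", "LONG"))
  acq <- acquisition_config(n_time_bins = 128, irf_fwhm = 0)
  fi <- fit_image(render_decay_stack(ph, acq), binning = 0)
  m_short <- mean(fi$tau_mean[ph$label_map == ph$legend[["SHORT"]]])
  m_long <- mean(fi$tau_mean[ph$label_map == ph$legend[["LONG"]]])
  expect_lt(abs(m_short - 1.0), 0.05)
  expect_lt(abs(m_long - 2.0), 0.10)
  expect_gt(m_long - m_short, 0.8)
})

test_that("lifetime-coded images are black when masked and hue-coded at endpoints", {
  tau <- matrix(c(0.5, 2.5, NA, 1.5), 2, 2)
  intensity <- matrix(c(10, 10, 10, 0), 2, 2)
  img <- lifetime_coded_image(tau, intensity, range = c(0.5, 2.5))
  expect_equal(img[2, 2, ], c(0, 0, 0))   # zero intensity -> black
  expect_equal(img[1, 2, ], c(0, 0, 0))   # NA tau -> black
  # endpoint hues of the documented map: blue at min, red at max
  expect_equal(img[1, 1, ], c(0, 0, 1))
  expect_equal(img[2, 1, ], c(1, 0, 0))

  const <- lifetime_coded_image(matrix(1.2, 3, 3), matrix(5, 3, 3))
  hues <- apply(matrix(const, ncol = 3), 1, function(px) {
    grDevices::rgb2hsv(px[1], px[2], px[3], maxColorValue = 1)[1]
  })
  expect_equal(length(unique(round(hues, 10))), 1)
  expect_error(lifetime_coded_image(tau, intensity, range = c(2, 1)), "min < max")
})
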