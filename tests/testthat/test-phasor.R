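test_that("phasor of canonical spectra lands on the known points", {
  flat <- spectrum_to_phasor(rep(1, 16))
  expect_equal(unname(flat), c(0, 0), tolerance = 1e-12)

  d1 <- spectrum_to_phasor(c(1, rep(0, 15)))
  expect_equal(unname(d1), c(1, 0), tolerance = 1e-12)

  d5 <- rep(0, 16); d5[5] <- 3          # k = 4 -> angle pi/2
  expect_equal(unname(spectrum_to_phasor(d5)), c(0, 1), tolerance = 1e-12)

  anti <- rep(0, 16); anti[1] <- 2; anti[9] <- 2
  expect_equal(unname(spectrum_to_phasor(anti)), c(0, 0), tolerance = 1e-12)

  expect_error(spectrum_to_phasor(rep(0, 16)), "zero total")
  expect_error(spectrum_to_phasor(c(1)), "at least 2")
})

test_that("phasors are scale-invariant, bounded by the unit disk, and mix linearly", {
  set.seed(5)
  for (i in 1:25) {
    a <- rexp(16); b <- rexp(16)
    pa <- spectrum_to_phasor(a)
    expect_equal(spectrum_to_phasor(a * runif(1, 0.1, 100)), pa,
                 tolerance = 1e-12)
    expect_lte(sum(pa^2), 1 + 1e-9)

    pb <- spectrum_to_phasor(b)
    pm <- spectrum_to_phasor(a + b)
    alpha <- sum(b) / (sum(a) + sum(b))   # fractional position toward b
    expect_equal(unname(pm), unname(pa + alpha * (pb - pa)),
                 tolerance = 1e-12)
  }
})

test_that("phasor_field matches a per-pixel brute-force oracle to 1e-12", {
  set.seed(31)
  stack <- array(rpois(32 * 32 * 16, 40), dim = c(32, 32, 16))
  stack[3, 5, ] <- 0                            # one invalid pixel
  field <- phasor_field(stack)
  for (i in seq_len(32)) {
    for (j in seq_len(32)) {
      if (sum(stack[i, j, ]) == 0) {
        expect_false(field$valid_mask[i, j])
        expect_true(is.na(field$G[i, j]))
      } else {
        gs <- spectrum_to_phasor(stack[i, j, ])
        expect_lt(abs(field$G[i, j] - gs[["G"]]), 1e-12)
        expect_lt(abs(field$S[i, j] - gs[["S"]]), 1e-12)
      }
    }
  }
})

test_that("uniform and all-zero stacks give degenerate fields", {
  uni <- array(rep(c(1, 3, 2, rep(1, 13)), each = 16), dim = c(4, 4, 16))
  f <- phasor_field(uni)
  expect_equal(length(unique(round(f$G[f$valid_mask], 12))), 1)
  expect_equal(length(unique(round(f$S[f$valid_mask], 12))), 1)

  f0 <- phasor_field(array(0, dim = c(4, 4, 16)))
  expect_false(any(f0$valid_mask))
})

test_that("phasor histograms conserve valid-pixel counts and localize modes", {
  set.seed(13)
  stack <- array(rpois(16 * 16 * 16, 30), dim = c(16, 16, 16))
  stack[1, 1, ] <- 0
  field <- phasor_field(stack)
  h <- phasor_histogram(field, 64)
  expect_equal(sum(h), sum(field$valid_mask))

  # uniform stack: single occupied bin
  uni <- array(rep(rexp(16), each = 9), dim = c(3, 3, 16))
  expect_equal(sum(phasor_histogram(phasor_field(uni), 32) > 0), 1)

  # two distinct emitters: modes within one bin of the analytic phasors
  models <- two_emitter_models()
  ph <- make_phantom("two_band", dim = c(40L, 40L), class_models = models,
                     seed = 17, classes = c("A", "B"))
  acq <- acq_small()
  stack <- render_spectral_stack(ph, acq)
  field <- phasor_field(stack)
  n_bins <- 64
  h <- phasor_histogram(field, n_bins)
  bin_w <- 2 / n_bins
  gc <- attr(h, "g_centers"); sc <- attr(h, "s_centers")
  for (cl in c("A", "B")) {
    truth <- spectrum_to_phasor(class_expected_spectrum(ph, cl, acq))
    mask <- ph$label_map == ph$legend[[cl]]
    sub <- table(
      factor(findInterval(field$G[mask], seq(-1, 1, length.out = n_bins + 1),
                          rightmost.closed = TRUE), levels = 1:n_bins),
      factor(findInterval(field$S[mask], seq(-1, 1, length.out = n_bins + 1),
                          rightmost.closed = TRUE), levels = 1:n_bins))
    mode_idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    expect_lt(abs(gc[mode_idx[1]] - truth["G"]), 1.5 * bin_w)
    expect_lt(abs(sc[mode_idx[2]] - truth["S"]), 1.5 * bin_w)
  }
})

test_that("gating assigns first-match labels and recovers a two-class phantom", {
  models <- two_emitter_models(brightness = 1e4)
  ph <- make_phantom("two_band", dim = c(50L, 50L), class_models = models,
                     seed = 23, classes = c("A", "B"))
  acq <- acq_small()
  field <- phasor_field(render_spectral_stack(ph, acq))

  # whole-disk gate labels every valid pixel
  all_gate <- list(gate_circle("ALL", c(0, 0), 1.5))
  lm_all <- apply_gates(field, all_gate)
  expect_true(all(lm_all$labels[field$valid_mask] == 1L))

  # far-away gate labels nothing
  none <- apply_gates(field, list(gate_circle("N", c(10, 10), 0.1)))
  expect_true(all(none$labels == 0L))

  # class-centered disjoint gates: >= 99% accuracy against ground truth
  gates <- lapply(c("A", "B"), function(cl) {
    gate_circle(cl, spectrum_to_phasor(class_expected_spectrum(ph, cl, acq)),
                radius = 0.06)
  })
  lm <- apply_gates(field, gates)
  pred <- names(lm$legend)[match(lm$labels, lm$legend)]
  truth <- names(ph$legend)[match(ph$label_map, ph$legend)]
  expect_gt(mean(pred == truth), 0.99)

  # polygon gate agrees with its own circle-ish region
  sq <- gate_polygon("SQ", rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)))
  lm_sq <- apply_gates(field, list(sq))
  expect_true(all(lm_sq$labels[field$valid_mask] == 1L))
  expect_error(gate_polygon("bad", rbind(c(0, 0), c(1, 1))), ">= 3")
})

test_that("strict gating errors on overlap; ordered gating is first-match-wins", {
  set.seed(2)
  stack <- array(rpois(8 * 8 * 16, 30), dim = c(8, 8, 16))
  field <- phasor_field(stack)
  g1 <- gate_circle("X", c(0, 0), 1.5)
  g2 <- gate_circle("Y", c(0, 0), 1.5)
  expect_error(apply_gates(field, list(g1, g2), strict = TRUE), "overlap")
  lm <- apply_gates(field, list(g1, g2))
  expect_true(all(lm$labels[field$valid_mask] == 1L))
})

test_that("segmented RGB back-projection weights gate colors by intensity", {
  set.seed(4)
  stack <- array(rpois(10 * 10 * 16, 25), dim = c(10, 10, 16))
  field <- phasor_field(stack)

  # all UNASSIGNED -> black image
  lm0 <- apply_gates(field, list(gate_circle("N", c(5, 5), 0.1)))
  expect_equal(segmented_rgb(stack, lm0), array(0, dim = c(10, 10, 3)))

  # one gate over a uniform-intensity stack -> constant color
  uni <- array(2, dim = c(6, 6, 16))
  fu <- phasor_field(uni)
  lmu <- apply_gates(fu, list(gate_circle("U", c(0, 0), 1.5,
                                          color = c(0.2, 0.5, 0.9))))
  img <- segmented_rgb(uni, lmu)
  expect_equal(unique(as.vector(img[, , 1])), 0.2)
  expect_equal(unique(as.vector(img[, , 3])), 0.9)

  # doubling intensity: hue (channel proportions) unchanged
  lm <- apply_gates(field, list(gate_circle("A", c(0, 0), 1.5,
                                            color = c(0.8, 0.4, 0.1))))
  img1 <- segmented_rgb(stack, lm)
  img2 <- segmented_rgb(stack * 2, lm)
  expect_equal(img1, img2)   # frame normalization cancels the doubling
})
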