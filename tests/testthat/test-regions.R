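test_that("classify_regions applies the three rules deterministically", {
  tau <- matrix(2, 4, 4)
  all_true <- matrix(TRUE, 4, 4)
  all_false <- matrix(FALSE, 4, 4)

  # no tumor interior, SHG everywhere -> all NOIR
  lm <- classify_regions(tau, all_true, all_false, 1.8, 1.5)
  expect_true(all(lm$labels == lm$legend[["NOIR"]]))

  # all interior, long lifetimes -> all IR
  lm <- classify_regions(tau, all_false, all_true, 1.8, 1.5)
  expect_true(all(lm$labels == lm$legend[["IR"]]))

  # short lifetimes, no SHG, no interior -> all NEIR
  lm <- classify_regions(matrix(1.0, 4, 4), all_false, all_false, 1.8, 1.5)
  expect_true(all(lm$labels == lm$legend[["NEIR"]]))

  # intermediate lifetime, no SHG -> UNASSIGNED
  lm <- classify_regions(matrix(1.65, 4, 4), all_false, all_false, 1.8, 1.5)
  expect_true(all(lm$labels == 0L))

  expect_error(classify_regions(tau, all_true, matrix(FALSE, 3, 3), 1.8, 1.5),
               "congruent")
  expect_error(classify_regions(tau, all_true, all_false, 1.5, 1.8), "<=")
})

test_that("a three-ring phantom is classified with >= 99% per-class agreement", {
  ph <- make_phantom("three_ring", dim = c(32L, 32L),
                     class_models = ring_models(), seed = 61)
  acq <- acquisition_config(n_time_bins = 128, irf_fwhm = 0)
  ch <- acq$channels
  dec <- render_decay_stack(ph, acq, channel = ch$tpef_max_channel)
  fi <- fit_image(dec, binning = 0)

  stack <- render_spectral_stack(ph, acq)
  noir_frac <- mean(ph$label_map == ph$legend[["NOIR"]])
  shg <- shg_presence_mask(stack, ch, quantile = 1 - noir_frac)
  boundary <- ph$label_map == ph$legend[["IR"]]

  lm <- classify_regions(fi$tau_mean, shg, boundary,
                         tau_threshold_long = 1.8, tau_threshold_short = 1.3)
  for (cl in c("NOIR", "NEIR", "IR")) {
    truth <- ph$label_map == ph$legend[[cl]]
    pred <- lm$labels == lm$legend[[cl]]
    expect_gt(mean(pred[truth]), 0.99)
  }
})

test_that("region_summary passes per-ROI tables through and averages maps per class", {
  df <- tibble::tibble(group = c("A", "A", "B"), value = c(1, 2, 3))
  expect_equal(region_summary(df), df)

  vals <- matrix(c(1, 2, 3, 4), 2, 2)
  lm <- label_map(matrix(c(1L, 1L, 2L, 0L), 2, 2),
                  c(UNASSIGNED = 0L, X = 1L, Y = 2L))
  rs <- region_summary(vals, lm)
  expect_equal(rs$value[rs$group == "X"], mean(c(1, 2)))
  expect_equal(rs$value[rs$group == "Y"], 3)

  vals[1, 2] <- NA
  expect_warning(rs2 <- region_summary(vals, lm), "empty")
  expect_false("Y" %in% rs2$group)
})

test_that("one-way ANOVA matches the textbook decomposition and its symmetries", {
  groups <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(3, 4, 5))
  hand <- anova_by_hand(groups)
  got <- one_way_anova(groups_to_df(groups))
  expect_equal(got$statistic, hand$F, tolerance = 1e-9)
  expect_equal(got$p.value, hand$p, tolerance = 1e-9)
  expect_equal(got$df_between, 2)
  expect_equal(got$df_within, 6)

  # permuting group order leaves F unchanged
  perm <- one_way_anova(groups_to_df(groups[c(3, 1, 2)]))
  expect_equal(perm$statistic, got$statistic, tolerance = 1e-12)

  # identical groups -> F = 0
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(one_way_anova(groups_to_df(same))$statistic, 0)

  expect_error(one_way_anova(tibble::tibble(group = "a", value = 1)),
               "at least 2")
})

test_that("Tukey HSD agrees with the studentized-range closed form for two groups", {
  g <- list(a = c(1.1, 2.0, 2.9, 1.7), b = c(3.2, 4.1, 3.6, 4.4))
  tk <- tukey_hsd(groups_to_df(g))
  tt <- t.test(g$b, g$a, var.equal = TRUE)
  p_range <- ptukey(sqrt(2) * abs(tt$statistic), 2, 6, lower.tail = FALSE)
  expect_equal(tk$p.adj, unname(p_range), tolerance = 1e-9)

  # identical groups -> all pairwise p approx 1
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  tk_same <- tukey_hsd(groups_to_df(same))
  expect_true(all(tk_same$p.adj > 0.999))

  # p matrix symmetric with unit diagonal
  groups <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(5, 6, 7))
  m <- tukey_p_matrix(tukey_hsd(groups_to_df(groups)))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
})

test_that("significance stars reproduce the caption thresholds with boundary demotion", {
  expect_equal(significance_stars(1e-6), "****")
  expect_equal(significance_stars(5e-5), "***")
  expect_equal(significance_stars(1e-3), "**")
  expect_equal(significance_stars(0.03), "*")
  expect_equal(significance_stars(0.2), "ns")
  # boundaries fall into the less significant bin
  expect_equal(significance_stars(c(1e-5, 1e-4, 1e-2, 0.05)),
               c("***", "**", "*", "ns"))
  expect_equal(significance_stars(c(0, 1)), c("****", "ns"))
  expect_error(significance_stars(1.2), "\\[0, 1\\]")
})

test_that("group_stats bundles descriptives, ANOVA and Tukey with SEM = sd/sqrt(n)", {
  groups <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  gs <- group_stats(groups_to_df(groups))
  expect_equal(gs$summary$mean, c(2, 5, 8))
  expect_equal(gs$summary$sem, rep(sd(c(1, 2, 3)) / sqrt(3), 3))
  expect_equal(glance(gs), gs$anova)
  expect_equal(tidy(gs), gs$tukey)
  expect_s3_class(autoplot(gs), "ggplot")
})
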