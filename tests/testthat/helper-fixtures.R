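# Shared fixtures: small acquisition geometries and single-purpose phantoms
# built in code so every test input carries its own ground truth.

acq_small <- function(n_time_bins = 128L) {
  acquisition_config(n_time_bins = n_time_bins)
}

# one-class phantom over the full frame
uniform_phantom <- function(class = "NORMAL", dim = c(32L, 32L), seed = 1L,
                            models = default_class_models()) {
  make_phantom(matrix(class, dim[1], dim[2]), class_models = models,
               seed = seed)
}

# two Gaussian emitters two channels (25 nm) apart, no SHG, for gating tests
two_emitter_models <- function(brightness = 1e4) {
  comps <- data.frame(fraction = c(0.5, 0.5), lifetime_ns = c(0.5, 2.5))
  list(
    A = list(list(species = fluorophore("A", 500, 60, comps, brightness),
                  weight = 1)),
    B = list(list(species = fluorophore("B", 525, 60, comps, brightness),
                  weight = 1))
  )
}

# three-ring models with well-separated lifetimes and SHG confined to NOIR;
# the default brightness puts ~2e4 photons in the FLIM channel per pixel
ring_models <- function(tpef_brightness = 1e5) {
  tpef <- function(center, a1) {
    fluorophore(sprintf("TPEF-%g", center), center, 60,
                data.frame(fraction = c(a1, 1 - a1),
                           lifetime_ns = c(0.5, 2.5)),
                tpef_brightness)
  }
  list(
    NOIR = list(list(species = tpef(505, 0.60), weight = 1),
                list(species = shg_species(6000), weight = 1)),
    NEIR = list(list(species = tpef(518, 0.80), weight = 1)),   # tau_mean 0.9
    IR = list(list(species = tpef(526, 0.15), weight = 1))      # tau_mean 2.2
  )
}

# textbook one-way ANOVA decomposition, independent of stats::aov
anova_by_hand <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ss_between <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - gm)^2
  }, numeric(1)))
  ss_within <- sum(vapply(groups, function(g) {
    sum((g - mean(g))^2)
  }, numeric(1)))
  df_b <- length(groups) - 1
  df_w <- length(all) - length(groups)
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(F = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

groups_to_df <- function(groups) {
  tibble::tibble(
    group = rep(names(groups), lengths(groups)),
    value = unlist(groups, use.names = FALSE)
  )
}
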