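#' Label map container
#'
#' An integer class-label image plus a legend mapping ids to class names.
#' Id 0 is reserved for UNASSIGNED.
#'
#' @param labels H x W integer matrix.
#' @param legend Named integer vector, name -> id, covering all ids present.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, legend) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  present <- unique(as.vector(labels))
  if (!all(present %in% legend)) stop("legend does not cover all label ids")
  structure(list(labels = labels, legend = legend), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  tab <- table(x$labels)
  nm <- names(x$legend)[match(names(tab), x$legend)]
  cat(sprintf("<label_map> %d x %d px: %s\n", nrow(x$labels), ncol(x$labels),
              paste(sprintf("%s=%s", nm, tab), collapse = ", ")))
  invisible(x)
}

#' @exportS3Method
as_tibble.label_map <- function(x, ...) {
  d <- dim(x$labels)
  tibble::tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    label = as.vector(x$labels),
    class = names(x$legend)[match(as.vector(x$labels), x$legend)]
  )
}

#' Rule-based classification of tumor regions
#'
#' Implements the three-way taxonomy used for basal cell carcinoma sections:
#' \itemize{
#'   \item IR (invasive region): pixels inside the tumor boundary whose mean
#'     fluorescence lifetime is long (`tau >= tau_threshold_long`);
#'   \item NOIR (non-invasive region): pixels outside the boundary where SHG
#'     (collagen) signal is present;
#'   \item NEIR (near-invasive region): remaining pixels — between the IR and
#'     the SHG-bearing surround — with a markedly shorter lifetime
#'     (`tau <= tau_threshold_short`).
#' }
#' Everything else is UNASSIGNED. Labels are mutually exclusive and the rules
#' are applied deterministically in the order above. No printed threshold
#' values exist for the lifetime cuts; they are explicit, required inputs.
#'
#' @param tau_map H x W mean-lifetime matrix (ns; `NA` allowed).
#' @param shg_mask H x W logical: SHG signal present.
#' @param boundary_mask H x W logical: tumor interior (inside the drawn
#'   boundary).
#' @param tau_threshold_long,tau_threshold_short Lifetime cuts in ns with
#'   `tau_threshold_short <= tau_threshold_long`.
#' @return A [label_map()] with legend UNASSIGNED=0, NOIR=1, NEIR=2, IR=3.
#' @export
classify_regions <- function(tau_map, shg_mask, boundary_mask,
                             tau_threshold_long, tau_threshold_short) {
  if (!identical(dim(tau_map), dim(shg_mask)) ||
      !identical(dim(tau_map), dim(boundary_mask))) {
    stop("tau_map, shg_mask and boundary_mask must be congruent")
  }
  if (tau_threshold_short > tau_threshold_long) {
    stop("tau_threshold_short must be <= tau_threshold_long")
  }
  lab <- matrix(0L, nrow(tau_map), ncol(tau_map))
  ir <- boundary_mask & !is.na(tau_map) & tau_map >= tau_threshold_long
  noir <- !boundary_mask & shg_mask & lab == 0L & !ir
  neir <- !ir & !noir & !is.na(tau_map) & tau_map <= tau_threshold_short
  lab[ir] <- 3L; lab[noir] <- 1L; lab[neir] <- 2L
  label_map(lab, c(UNASSIGNED = 0L, NOIR = 1L, NEIR = 2L, IR = 3L))
}

#' SHG presence mask from the SHG channel
#'
#' Thresholds the SHG channel (channel 2 by default) at a quantile of the
#' frame's intensity distribution; the instrument literature prints no
#' threshold, so the cut is an explicit parameter.
#'
#' @param stack H x W x omega spectral stack.
#' @param channels A [spectral_channels()] map.
#' @param quantile Intensity quantile above which SHG counts as present
#'   (default 0.9).
#' @return H x W logical matrix.
#' @export
shg_presence_mask <- function(stack, channels = spectral_channels(),
                              quantile = 0.9) {
  plane <- stack[, , channels$shg_channel]
  plane > stats::quantile(plane, quantile)
}

#' Per-group samples from a value map or per-ROI table
#'
#' The statistical unit is a field of view / region of interest, never a
#' pixel: pixel-level inference on spatially correlated maps would be grossly
#' pseudo-replicated. Given a per-ROI tibble (columns `group`, `value`) the
#' table is passed through with empty groups dropped; given a value map plus a
#' [label_map()], one summary value (the mean over the class's pixels) is
#' returned per class — suitable when each map is itself one field of view and
#' samples are accumulated over maps.
#'
#' @param x A data frame with columns `group` and `value`, or an H x W value
#'   matrix.
#' @param labels A [label_map()] (required when `x` is a matrix).
#' @return Tibble with columns `group`, `value`.
#' @export
region_summary <- function(x, labels = NULL) {
  if (is.data.frame(x)) {
    out <- tibble::as_tibble(x)[, c("group", "value")]
  } else {
    stopifnot(inherits(labels, "label_map"),
              identical(dim(x), dim(labels$labels)))
    ids <- setdiff(sort(unique(as.vector(labels$labels))), 0L)
    out <- tibble::tibble(
      group = names(labels$legend)[match(ids, labels$legend)],
      value = vapply(ids, function(id) {
        mean(x[labels$labels == id], na.rm = TRUE)
      }, numeric(1))
    )
  }
  empty <- is.na(out$value)
  if (any(empty)) {
    warning(sprintf("dropping empty group(s): %s",
                    paste(unique(out$group[empty]), collapse = ", ")))
    out <- out[!empty, ]
  }
  out
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (between/within mean-square ratio)
#' across the groups of a `group`/`value` table, via [stats::aov()].
#'
#' @param data Data frame with columns `group` and `value`.
#' @return One-row tibble: `statistic` (F), `p.value`, `df_between`,
#'   `df_within`.
#' @export
one_way_anova <- function(data) {
  data <- prep_groups(data)
  fit <- stats::aov(value ~ group, data = data)
  s <- summary(fit)[[1]]
  tibble::tibble(statistic = s$`F value`[1], p.value = s$`Pr(>F)`[1],
                 df_between = s$Df[1], df_within = s$Df[2])
}

#' Tukey's honestly-significant-difference multiple comparisons
#'
#' All pairwise group comparisons with studentized-range adjusted p-values,
#' via [stats::TukeyHSD()] on the one-way fit.
#'
#' @param data Data frame with columns `group` and `value`.
#' @return Tibble with `group1`, `group2`, `estimate` (mean difference),
#'   `conf.low`, `conf.high`, `p.adj`, `stars`.
#' @export
tukey_hsd <- function(data) {
  data <- prep_groups(data)
  tk <- stats::TukeyHSD(stats::aov(value ~ group, data = data))$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tibble::tibble(
    group1 = vapply(pairs, `[`, "", 1),
    group2 = vapply(pairs, `[`, "", 2),
    estimate = tk[, "diff"],
    conf.low = tk[, "lwr"], conf.high = tk[, "upr"],
    p.adj = tk[, "p adj"],
    stars = significance_stars(pmin(pmax(tk[, "p adj"], 0), 1))
  )
}

#' Symmetric matrix of Tukey adjusted p-values
#'
#' @param comparisons Output of [tukey_hsd()].
#' @return Square symmetric matrix with unit diagonal.
#' @export
tukey_p_matrix <- function(comparisons) {
  groups <- sort(unique(c(comparisons$group1, comparisons$group2)))
  m <- matrix(1, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_len(nrow(comparisons))) {
    m[comparisons$group1[i], comparisons$group2[i]] <- comparisons$p.adj[i]
    m[comparisons$group2[i], comparisons$group1[i]] <- comparisons$p.adj[i]
  }
  m
}

prep_groups <- function(data) {
  stopifnot(all(c("group", "value") %in% names(data)))
  data <- data[!is.na(data$value), ]
  data$group <- factor(data$group)
  if (nlevels(data$group) < 2L) stop("need at least 2 groups")
  n <- table(data$group)
  if (any(n < 2L)) stop("each group needs at least 2 observations")
  data
}

#' Significance star labels
#'
#' Maps p-values to the star convention used in the figure annotations:
#' `****` for p < 0.00001, `***` for 0.00001 <= p < 0.0001, `**` for
#' 0.0001 <= p < 0.01, `*` for 0.01 <= p < 0.05, `ns` otherwise. Boundary
#' values fall in the less-significant bin.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  as.character(cut(p, breaks = c(0, 1e-5, 1e-4, 1e-2, 0.05, 1),
                   labels = c("****", "***", "**", "*", "ns"),
                   right = FALSE, include.lowest = TRUE))
}

#' Full group statistics: descriptives, ANOVA, Tukey
#'
#' @param data Data frame with columns `group` and `value`.
#' @return An object of class `group_stats` with elements `summary` (per-group
#'   n, mean, sem), `anova`, `tukey`; `tidy()` returns the Tukey table,
#'   `glance()` the ANOVA row.
#' @export
group_stats <- function(data) {
  data <- prep_groups(data)
  summ <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(data), group),
    n = dplyr::n(), mean = mean(value),
    sem = stats::sd(value) / sqrt(dplyr::n()), .groups = "drop")
  structure(list(summary = summ, anova = one_way_anova(data),
                 tukey = tukey_hsd(data)),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat("<group_stats>\n")
  print(x$summary)
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$anova$df_between, x$anova$df_within, x$anova$statistic,
              x$anova$p.value))
  print(x$tukey[, c("group1", "group2", "estimate", "p.adj", "stars")])
  invisible(x)
}

#' @exportS3Method
tidy.group_stats <- function(x, ...) x$tukey

#' @exportS3Method
glance.group_stats <- function(x, ...) x$anova
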