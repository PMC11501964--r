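#' Spectral phasor coordinates of a single spectrum
#'
#' Projects an emission spectrum onto the n-th Fourier harmonic: with channel
#' index k = 0..omega-1 and phase 2*pi*n*k/omega,
#' \deqn{G = \sum_k I_k \cos(2\pi n k/\omega) / \sum_k I_k, \quad
#'       S = \sum_k I_k \sin(2\pi n k/\omega) / \sum_k I_k.}
#' The pair (G, S) places the spectrum inside the unit disk; similar spectra
#' map to nearby points, and the transform is invariant to intensity scaling.
#' The phase origin is channel 1 (a different origin only rotates the plot).
#'
#' @param spectrum Nonnegative omega-vector of channel intensities with a
#'   positive sum.
#' @param harmonic Positive integer harmonic (default 1, the first harmonic).
#' @return Named numeric vector `c(G = , S = )`.
#' @examples
#' spectrum_to_phasor(rep(1, 16))            # flat spectrum -> origin
#' spectrum_to_phasor(c(1, rep(0, 15)))      # delta at channel 1 -> (1, 0)
#' @export
spectrum_to_phasor <- function(spectrum, harmonic = 1L) {
  spectrum <- as.numeric(spectrum)
  omega <- length(spectrum)
  if (omega < 2L) stop("need at least 2 spectral channels")
  if (any(spectrum < 0)) stop("spectrum must be nonnegative")
  total <- sum(spectrum)
  if (total <= 0) stop("spectrum has zero total intensity")
  phase <- 2 * pi * harmonic * (seq_len(omega) - 1) / omega
  c(G = sum(spectrum * cos(phase)) / total,
    S = sum(spectrum * sin(phase)) / total)
}

#' Per-pixel phasor field of a spectral stack
#'
#' Applies the spectral phasor transform to every pixel of an H x W x omega
#' stack in one matrix product. Pixels with zero total intensity are masked
#' invalid and carry no coordinate (they are never mapped to the origin, which
#' would fabricate a cluster there).
#'
#' @param stack H x W x omega array of nonnegative counts.
#' @param harmonic Positive integer harmonic.
#' @return An object of class `phasor_field`: `G`, `S` (H x W matrices, `NA`
#'   where invalid), `total_intensity`, `valid_mask`, `harmonic`.
#' @export
phasor_field <- function(stack, harmonic = 1L) {
  stack <- check_stack(stack)
  d <- dim(stack)
  omega <- d[3]
  phase <- 2 * pi * harmonic * (seq_len(omega) - 1) / omega
  flat <- matrix(stack, ncol = omega)
  total <- rowSums(flat)
  valid <- total > 0
  g <- s <- rep(NA_real_, length(total))
  g[valid] <- (flat %*% cos(phase))[valid] / total[valid]
  s[valid] <- (flat %*% sin(phase))[valid] / total[valid]
  structure(
    list(G = matrix(g, d[1], d[2]), S = matrix(s, d[1], d[2]),
         total_intensity = matrix(total, d[1], d[2]),
         valid_mask = matrix(valid, d[1], d[2]),
         harmonic = as.integer(harmonic)),
    class = "phasor_field"
  )
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf("<phasor_field> %d x %d px, harmonic %d, %d valid pixels\n",
              nrow(x$G), ncol(x$G), x$harmonic, sum(x$valid_mask)))
  invisible(x)
}

#' @exportS3Method
as_tibble.phasor_field <- function(x, ...) {
  d <- dim(x$G)
  tibble::tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    G = as.vector(x$G), S = as.vector(x$S),
    total_intensity = as.vector(x$total_intensity),
    valid = as.vector(x$valid_mask)
  )
}

#' 2-D histogram of a phasor field over the unit square
#'
#' @param field A [phasor_field()].
#' @param n_bins Bins per axis (>= 2) over \[-1, 1\].
#' @return `n_bins` x `n_bins` count matrix (rows = G bins, cols = S bins)
#'   with bin-center coordinates in attributes `g_centers`, `s_centers`; the
#'   total count equals the number of valid pixels.
#' @export
phasor_histogram <- function(field, n_bins = 128L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("need at least 2 bins per axis")
  breaks <- seq(-1, 1, length.out = n_bins + 1)
  g <- field$G[field$valid_mask]
  s <- field$S[field$valid_mask]
  gi <- pmin(pmax(findInterval(g, breaks, rightmost.closed = TRUE), 1L), n_bins)
  si <- pmin(pmax(findInterval(s, breaks, rightmost.closed = TRUE), 1L), n_bins)
  h <- matrix(0L, n_bins, n_bins)
  tab <- table(factor(gi, levels = seq_len(n_bins)),
               factor(si, levels = seq_len(n_bins)))
  h[] <- as.integer(tab)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  attr(h, "g_centers") <- centers
  attr(h, "s_centers") <- centers
  h
}

#' Phasor gates
#'
#' A gate is a geometric region of the (G, S) plane used to assign pixels to a
#' structural class: a circle (`gate_circle`) or a polygon (`gate_polygon`).
#' Each gate carries a label and an RGB color used when gated pixels are
#' back-projected into the image.
#'
#' @param label Class name.
#' @param center Length-2 numeric `(g, s)` circle center.
#' @param radius Circle radius (> 0).
#' @param vertices Matrix with >= 3 rows of `(g, s)` polygon vertices.
#' @param color Length-3 RGB in \[0, 1\].
#' @return An object of class `phasor_gate`.
#' @export
gate_circle <- function(label, center, radius, color = c(1, 1, 1)) {
  if (radius <= 0) stop("gate radius must be positive")
  structure(list(label = label, shape = "circle", center = as.numeric(center),
                 radius = radius, color = as.numeric(color)),
            class = "phasor_gate")
}

#' @rdname gate_circle
#' @export
gate_polygon <- function(label, vertices, color = c(1, 1, 1)) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L) {
    stop("polygon gate needs >= 3 (g, s) vertices")
  }
  structure(list(label = label, shape = "polygon", vertices = vertices,
                 color = as.numeric(color)),
            class = "phasor_gate")
}

# vectorized even-odd ray casting
points_in_polygon <- function(g, s, vertices) {
  n <- nrow(vertices)
  inside <- rep(FALSE, length(g))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    crosses <- ((yi > s) != (yj > s)) &
      (g < (xj - xi) * (s - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

gate_contains <- function(gate, g, s) {
  if (gate$shape == "circle") {
    (g - gate$center[1])^2 + (s - gate$center[2])^2 <= gate$radius^2
  } else {
    points_in_polygon(g, s, gate$vertices)
  }
}

#' Segment a phasor field with an ordered set of gates
#'
#' Every valid pixel receives the label of the first gate (in list order) that
#' contains its (G, S) coordinate; pixels matched by no gate, and invalid
#' pixels, are UNASSIGNED (id 0). With `strict = TRUE` an error is raised if
#' any pixel falls inside more than one gate.
#'
#' @param field A [phasor_field()].
#' @param gates Nonempty list of [gate_circle()]/[gate_polygon()] gates.
#' @param strict Error on overlapping gate membership instead of
#'   first-match-wins.
#' @return A `label_map` object (see [label_map()]): integer matrix plus
#'   legend with UNASSIGNED = 0 and gate labels 1..n in gate order, and the
#'   gate colors as attribute `colors`.
#' @export
apply_gates <- function(field, gates, strict = FALSE) {
  if (length(gates) == 0) stop("need at least one gate")
  g <- field$G[field$valid_mask]
  s <- field$S[field$valid_mask]
  assigned <- rep(0L, length(g))
  for (i in seq_along(gates)) {
    inside <- gate_contains(gates[[i]], g, s)
    if (strict && any(inside & assigned > 0L)) {
      stop("overlapping gates in strict mode")
    }
    assigned[inside & assigned == 0L] <- i
  }
  labels <- matrix(0L, nrow(field$G), ncol(field$G))
  labels[field$valid_mask] <- assigned
  legend <- c(UNASSIGNED = 0L,
              stats::setNames(seq_along(gates),
                              vapply(gates, `[[`, "", "label")))
  lm <- label_map(labels, legend)
  attr(lm, "colors") <- lapply(gates, `[[`, "color")
  lm
}

#' Back-project gated labels into an RGB image
#'
#' Each labeled pixel takes its gate's color scaled by the pixel's total
#' intensity normalized to the frame maximum; UNASSIGNED pixels are black.
#' Doubling all intensities leaves hue unchanged and only rescales value.
#'
#' @param stack The spectral stack the field was computed from (used for the
#'   intensity weighting), or `NULL` to use the field's `total_intensity`.
#' @param labels A `label_map` from [apply_gates()].
#' @param colors List of RGB triples per gate id; defaults to the colors
#'   attached by [apply_gates()].
#' @return H x W x 3 array in \[0, 1\].
#' @export
segmented_rgb <- function(stack, labels, colors = attr(labels, "colors")) {
  lab <- labels$labels
  if (is.null(stack)) {
    intensity <- matrix(1, nrow(lab), ncol(lab))
  } else {
    stack <- check_stack(stack)
    if (!identical(dim(stack)[1:2], dim(lab))) stop("shape mismatch")
    intensity <- apply(stack, c(1, 2), sum)
  }
  m <- max(intensity)
  if (m > 0) intensity <- intensity / m
  out <- array(0, dim = c(nrow(lab), ncol(lab), 3L))
  for (i in seq_along(colors)) {
    sel <- lab == i
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[sel] <- colors[[i]][ch] * intensity[sel]
      out[, , ch] <- plane
    }
  }
  out
}
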