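# TIFF + JSON-sidecar I/O.
#
# Values are stored as 32-bit TIFF pages scaled into [0, 1] by a power-of-two
# factor recorded in the sidecar. The sidecar also records whether the data
# were integer photon counts; those are re-rounded on read, so counts
# round-trip exactly.

sidecar_path <- function(path) paste0(path, ".json")

pow2_scale <- function(m) 2^max(ceiling(log2(max(m, 1) + 1)), 0)

write_pages <- function(arr, path, scale) {
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
}

read_pages <- function(path, scale, integer = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * scale
  if (integer) arr <- round(arr)
  arr
}

is_integer_valued <- function(x) all(x == round(x))

#' Write / read a spectral stack as multipage TIFF with JSON sidecar
#'
#' One TIFF page per spectral channel; the sidecar (`<path>.json`) records the
#' channel centers, the intensity scale factor, the seed and any extra
#' metadata, and is validated against the TIFF on read.
#'
#' @param stack H x W x omega array of counts.
#' @param path Output TIFF path.
#' @param channels A [spectral_channels()] map.
#' @param seed Seed to record for provenance.
#' @param extra Named list of additional metadata to store.
#' @return `write_spectral_stack` returns `path` invisibly;
#'   `read_spectral_stack` returns a list with `stack`, `channels` (the
#'   recorded centers), and `metadata`.
#' @export
write_spectral_stack <- function(stack, path,
                                 channels = spectral_channels(),
                                 seed = NA_integer_, extra = list()) {
  stack <- check_stack(stack, channels$n_channels)
  scale <- pow2_scale(max(stack))
  write_pages(stack, path, scale)
  meta <- c(list(kind = "spectral_stack", n_channels = channels$n_channels,
                 channel_centers_nm = channels$centers, scale = scale,
                 integer = is_integer_valued(stack), seed = seed), extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_sidecar <- function(path, kind) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop(sprintf("missing sidecar metadata file '%s'", sc))
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!identical(meta$kind, kind)) {
    stop(sprintf("sidecar '%s' describes '%s', expected '%s'", sc, meta$kind,
                 kind))
  }
  meta
}

#' @rdname write_spectral_stack
#' @export
read_spectral_stack <- function(path) {
  meta <- read_sidecar(path, "spectral_stack")
  arr <- read_pages(path, meta$scale, isTRUE(meta$integer))
  if (dim(arr)[3] != meta$n_channels) {
    stop(sprintf("TIFF has %d channels but metadata declares %d",
                 dim(arr)[3], meta$n_channels))
  }
  list(stack = arr, channels = meta$channel_centers_nm, metadata = meta)
}

#' Write / read a TCSPC decay stack as multipage TIFF with JSON sidecar
#'
#' One TIFF page per time bin; bin width and offset live in the sidecar.
#'
#' @param stack A `decay_stack` object.
#' @param path Output TIFF path.
#' @param seed,extra As in [write_spectral_stack()].
#' @return `write_decay_stack` returns `path` invisibly; `read_decay_stack`
#'   returns a `decay_stack` (with `config = NULL`) plus metadata in attribute
#'   `metadata`.
#' @export
write_decay_stack <- function(stack, path, seed = NA_integer_,
                              extra = list()) {
  stopifnot(inherits(stack, "decay_stack"))
  scale <- pow2_scale(max(stack$counts))
  write_pages(stack$counts, path, scale)
  meta <- c(list(kind = "decay_stack", n_time_bins = dim(stack$counts)[3],
                 bin_width_ns = stack$bin_width, t0_ns = stack$t0,
                 scale = scale, integer = is_integer_valued(stack$counts),
                 seed = seed), extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_decay_stack
#' @export
read_decay_stack <- function(path) {
  meta <- read_sidecar(path, "decay_stack")
  arr <- read_pages(path, meta$scale, isTRUE(meta$integer))
  if (dim(arr)[3] != meta$n_time_bins) {
    stop(sprintf("TIFF has %d time bins but metadata declares %d",
                 dim(arr)[3], meta$n_time_bins))
  }
  out <- structure(list(counts = arr, bin_width = meta$bin_width_ns,
                        t0 = meta$t0_ns, config = NULL),
                   class = "decay_stack")
  attr(out, "metadata") <- meta
  out
}

#' Write / read a label map as a single-page TIFF with JSON sidecar
#'
#' @param labels A [label_map()].
#' @param path Output TIFF path.
#' @return `write_label_map` returns `path` invisibly; `read_label_map`
#'   returns the [label_map()].
#' @export
write_label_map <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  scale <- pow2_scale(max(labels$labels))
  tiff::writeTIFF(labels$labels / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(kind = "label_map", scale = scale,
         legend = as.list(labels$legend)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  meta <- read_sidecar(path, "label_map")
  m <- tiff::readTIFF(path)
  legend <- unlist(meta$legend)
  label_map(round(m * meta$scale), stats::setNames(as.integer(legend),
                                                   names(legend)))
}

#' Stitch a grid of image tiles with linear feather blending
#'
#' Tiles of identical size are placed on a regular grid in which adjacent
#' tiles overlap by `overlap` of the tile extent (step = `round(size * (1 -
#' overlap))`; mosaic extent = `step * (n - 1) + size` per axis). In overlap
#' zones each tile's contribution is weighted by a linear ramp rising from its
#' edges, and the accumulated image is divided by the accumulated weight, so
#' constant inputs stitch to the same constant.
#'
#' @param tiles List of H x W matrices (or H x W x C arrays), row-major tile
#'   order.
#' @param grid `c(rows, cols)` of the tile grid; `length(tiles)` must equal
#'   `prod(grid)`.
#' @param overlap Fractional overlap in \[0, 0.5).
#' @return The stitched mosaic (matrix or array matching the tile dimension).
#' @export
stitch_tiles <- function(tiles, grid, overlap = 0.2) {
  if (overlap < 0 || overlap >= 0.5) stop("overlap must be in [0, 0.5)")
  if (length(tiles) != prod(grid)) stop("tile count does not match grid")
  dims <- lapply(tiles, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("all tiles must share the same shape")
  }
  d <- dims[[1]]
  is3d <- length(d) == 3L
  h <- d[1]; w <- d[2]; nc <- if (is3d) d[3] else 1L
  step_r <- if (grid[1] > 1) round(h * (1 - overlap)) else h
  step_c <- if (grid[2] > 1) round(w * (1 - overlap)) else w
  H <- step_r * (grid[1] - 1) + h
  W <- step_c * (grid[2] - 1) + w

  ramp <- function(n, m) {
    # linear feather over the overlap margin m, never exactly zero
    wts <- rep(1, n)
    if (m > 0) {
      edge <- seq_len(m) / (m + 1)
      wts[seq_len(m)] <- edge
      wts[n + 1 - seq_len(m)] <- edge
    }
    wts
  }
  wr <- ramp(h, h - step_r)
  wc <- ramp(w, w - step_c)
  tile_w <- outer(wr, wc)

  acc <- array(0, dim = c(H, W, nc))
  wacc <- matrix(0, H, W)
  k <- 1L
  for (r in seq_len(grid[1])) {
    for (cc in seq_len(grid[2])) {
      ri <- (r - 1) * step_r + seq_len(h)
      ci <- (cc - 1) * step_c + seq_len(w)
      tile <- tiles[[k]]
      for (ch in seq_len(nc)) {
        plane <- if (is3d) tile[, , ch] else tile
        acc[ri, ci, ch] <- acc[ri, ci, ch] + plane * tile_w
      }
      wacc[ri, ci] <- wacc[ri, ci] + tile_w
      k <- k + 1L
    }
  }
  for (ch in seq_len(nc)) acc[, , ch] <- acc[, , ch] / wacc
  if (is3d) acc else acc[, , 1]
}
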