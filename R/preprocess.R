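#' Brightness factor from a reference image
#'
#' A weak nuclear stain hurts segmentation, so all nuclear images in a run
#' are scaled by one shared constant derived from a user-chosen reference
#' image. The rule implemented here is quantile normalisation: the factor
#' maps the `quantile`-quantile of the reference's non-zero pixels to
#' `target_fraction` of the dtype ceiling,
#' `f = target_fraction * dtype_max / Q`, capped to `[1, 100]`. Using a
#' high quantile of the non-zero pixels makes the rule robust to hot
#' pixels and to large empty background areas.
#'
#' @param reference single-channel matrix in native units, or a
#'   [multichannel_image] (its first channel is used)
#' @param target_fraction fraction of the dtype ceiling the reference
#'   quantile is mapped to (default 0.875)
#' @param quantile quantile of the non-zero reference pixels (default 0.99)
#' @param dtype_max dtype ceiling; taken from the image when a
#'   [multichannel_image] is given
#' @return a scalar factor in `[1, 100]`
#' @export
compute_brightness_factor <- function(reference, target_fraction = 0.875,
                                      quantile = 0.99, dtype_max = 255) {
  if (inherits(reference, "multichannel_image")) {
    dtype_max <- reference$dtype_max
    reference <- get_channel(reference, 1L)
  }
  if (length(reference) == 0L) stop("reference image is empty")
  stopifnot(quantile > 0, quantile < 1,
            target_fraction > 0, target_fraction <= 1)
  nz <- reference[reference > 0]
  if (length(nz) == 0L) {
    warning("all-zero reference image; brightness factor set to 1")
    return(1.0)
  }
  q <- stats::quantile(nz, probs = quantile, names = FALSE)
  min(max(target_fraction * dtype_max / q, 1), 100)
}

#' Scale image brightness with clipping
#'
#' Multiplies every pixel by `factor` and clips to `[0, dtype_max]`.
#' Pixelwise ordering is preserved wherever no clipping occurs.
#'
#' @param image single-channel matrix in native units
#' @param factor positive scale factor
#' @param dtype_max dtype ceiling for clipping
#' @return matrix of the same shape
#' @export
apply_brightness <- function(image, factor, dtype_max = 255) {
  if (factor <= 0) stop("`factor` must be positive")
  pmin(pmax(image * factor, 0), dtype_max)
}

#' Split an image into overlapping tiles
#'
#' Tiles of size `tile_size` are laid on a grid with stride
#' `tile_size - overlap`; the last row/column of tiles is shifted inward so
#' tiles never exceed the image (no padding pixels are ever synthesised).
#' Each tile carries a *core* rectangle in parent coordinates inside which
#' it is authoritative: interior core edges sit at the midline of each
#' overlap band and image-border edges extend to the border, so the cores
#' partition the image exactly while the tiles cover it with overlap.
#'
#' @param image `H x W` matrix (a single channel)
#' @param tile_size tile edge length in pixels (default 512)
#' @param overlap overlap between adjacent tiles in pixels (default 64);
#'   must satisfy `tile_size > 2 * overlap >= 0`
#' @return list of tiles; each tile is a list with `pixels` (the crop),
#'   `row_off`/`col_off` (0-based offsets of the crop origin in the parent)
#'   and `core = c(row0, row1, col0, col1)` (1-based inclusive parent
#'   coordinates)
#' @export
tile_image <- function(image, tile_size = 512L, overlap = 64L) {
  if (overlap < 0 || tile_size <= 2 * overlap)
    stop("require tile_size > 2 * overlap >= 0")
  H <- nrow(image); W <- ncol(image)
  axis_starts <- function(n) {
    if (n <= tile_size) return(1L)
    stride <- tile_size - overlap
    s <- seq.int(1L, n - tile_size + 1L, by = stride)
    if (s[length(s)] + tile_size - 1L < n) s <- c(s, n - tile_size + 1L)
    unique(s)
  }
  core_bounds <- function(starts, n) {
    k <- length(starts)
    len <- min(tile_size, n)
    lo <- numeric(k); hi <- numeric(k)
    lo[1] <- 1L; hi[k] <- n
    if (k > 1L) for (i in 1:(k - 1L)) {
      band_lo <- starts[i + 1L]           # overlap band between tile i, i+1
      band_hi <- starts[i] + len - 1L
      mid <- (band_lo + band_hi) %/% 2L
      hi[i] <- mid; lo[i + 1L] <- mid + 1L
    }
    cbind(lo, hi)
  }
  rs <- axis_starts(H); cs <- axis_starts(W)
  rb <- core_bounds(rs, H); cb <- core_bounds(cs, W)
  th <- min(tile_size, H); tw <- min(tile_size, W)
  tiles <- list()
  for (i in seq_along(rs)) for (j in seq_along(cs)) {
    r0 <- rs[i]; c0 <- cs[j]
    tiles[[length(tiles) + 1L]] <- structure(list(
      pixels = image[r0:(r0 + th - 1L), c0:(c0 + tw - 1L), drop = FALSE],
      row_off = r0 - 1L, col_off = c0 - 1L,
      core = unname(c(rb[i, 1], rb[i, 2], cb[j, 1], cb[j, 2]))
    ), class = "image_tile")
  }
  tiles
}
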