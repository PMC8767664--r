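#' Construct a multi-channel image
#'
#' The container used throughout the pipeline for raw imaging data: an
#' `H x W x C` numeric array of non-negative intensities in native units
#' (e.g. 0--255 for 8-bit data), a channel name per plane, and the maximum
#' representable intensity of the source dtype.
#'
#' @param pixels numeric array `H x W x C`, or an `H x W` matrix (treated as
#'   a single channel). Rows index image rows (y), columns index image
#'   columns (x).
#' @param channel_names character vector of length `C`. Defaults to
#'   `"ch0" .. "ch{C-1}"`.
#' @param dtype_max maximum representable intensity (255 for 8-bit,
#'   65535 for 16-bit).
#' @return an object of class `multichannel_image` with fields `pixels`,
#'   `channel_names`, `dtype_max`.
#' @export
multichannel_image <- function(pixels, channel_names = NULL, dtype_max = 255) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  if (length(dim(pixels)) != 3L)
    stop("`pixels` must be an H x W x C array or an H x W matrix")
  d <- dim(pixels)
  if (any(d < 1L)) stop("image dimensions must all be >= 1")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(d[3]) - 1L)
  if (length(channel_names) != d[3])
    stop("length(channel_names) must equal the number of channels")
  if (dtype_max <= 0) stop("`dtype_max` must be positive")
  if (min(pixels) < 0 || max(pixels) > dtype_max)
    stop("pixel values must lie in [0, dtype_max]")
  structure(
    list(pixels = pixels, channel_names = as.character(channel_names),
         dtype_max = dtype_max),
    class = "multichannel_image"
  )
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<multichannel_image> %d x %d, %d channel(s), dtype_max = %s\n",
              d[1], d[2], d[3], format(x$dtype_max)))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.multichannel_image <- function(x) dim(x$pixels)

#' Extract one channel as a plain matrix
#' @param image a `multichannel_image`
#' @param channel channel index (1-based) or channel name
#' @return `H x W` numeric matrix in native intensity units
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "multichannel_image"))
  if (is.character(channel)) {
    idx <- match(channel, image$channel_names)
    if (is.na(idx)) stop("unknown channel name: ", channel)
    channel <- idx
  }
  if (channel < 1 || channel > dim(image$pixels)[3])
    stop("channel index out of range: ", channel)
  image$pixels[, , channel]
}

## ---- label images -----------------------------------------------------

#' Validate a label image
#'
#' A label image is an `H x W` integer matrix where 0 is background and each
#' positive id marks the pixels of one cell instance. Ids are unique within
#' an image but need not be consecutive.
#'
#' @param labels integer matrix
#' @return the label matrix, invisibly, after validation
#' @export
validate_label_image <- function(labels) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  if (any(labels < 0)) stop("label values must be non-negative")
  if (any(labels != floor(labels))) stop("label values must be integers")
  invisible(labels)
}

#' Distinct non-zero ids of a label image, ascending
#' @param labels label matrix
#' @return sorted integer vector of cell ids
#' @export
label_ids <- function(labels) {
  ids <- unique(as.integer(labels))
  sort(ids[ids > 0L])
}

#' Per-cell centroids of a label image
#'
#' Centroids are unrounded arithmetic means of pixel coordinates, reported
#' in 1-based matrix coordinates (`row`, `col`). Conversion to the 0-based
#' `(x, y)` convention of the cell table happens at quantification time.
#'
#' @param labels label matrix
#' @return data.frame with columns `id`, `row`, `col`
#' @export
label_centroids <- function(labels) {
  fg <- which(labels > 0L)
  if (length(fg) == 0L)
    return(data.frame(id = integer(), row = numeric(), col = numeric()))
  ids <- as.integer(labels[fg])
  H <- nrow(labels)
  rows <- ((fg - 1L) %% H) + 1L
  cols <- ((fg - 1L) %/% H) + 1L
  rs <- rowsum(cbind(rows, cols, 1), ids)
  uid <- as.integer(rownames(rs))
  data.frame(id = uid, row = rs[, 1] / rs[, 3], col = rs[, 2] / rs[, 3])
}

# Boundary pixels under the 4-neighbour rule: a labelled pixel whose north,
# south, east or west neighbour carries a different label or background;
# out-of-image counts as background.
label_boundary <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  p <- matrix(0L, H + 2L, W + 2L)
  p[2:(H + 1L), 2:(W + 1L)] <- labels
  ctr <- p[2:(H + 1L), 2:(W + 1L)]
  up    <- p[1:H,        2:(W + 1L)]
  down  <- p[3:(H + 2L), 2:(W + 1L)]
  left  <- p[2:(H + 1L), 1:W]
  right <- p[2:(H + 1L), 3:(W + 2L)]
  ctr > 0L & (up != ctr | down != ctr | left != ctr | right != ctr)
}

# Linear-index 8-neighbourhood expansion restricted to the image grid.
neighbor_indices8 <- function(idx, H, W) {
  if (length(idx) == 0L) return(integer())
  r <- ((idx - 1L) %% H) + 1L
  c <- ((idx - 1L) %/% H) + 1L
  out <- integer(0)
  for (dr in -1L:1L) for (dc in -1L:1L) {
    if (dr == 0L && dc == 0L) next
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    out <- c(out, (cc[ok] - 1L) * H + rr[ok])
  }
  unique(out)
}
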