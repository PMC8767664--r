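#' Deterministic classical nucleus segmentation
#'
#' The built-in segmentation backend: Gaussian smoothing, an Otsu
#' threshold, a Euclidean distance transform of the foreground, seeds at
#' distance-transform maxima separated by at least `min_seed_distance`
#' pixels, and a watershed on the negated distance transform restricted to
#' the foreground. Deterministic given identical input, so tiled runs,
#' stitching and the whole downstream pipeline are reproducible. A trained
#' learning-based segmenter can replace it through the backend contract
#' (see [segmenter_backend]).
#'
#' By default the Otsu threshold is computed from the input itself. When
#' segmenting tiles of a larger image, pass the threshold computed once on
#' the full image ([global_threshold]) so that every tile cuts foreground
#' at the same level and tiling cannot change the segmentation; the
#' pipeline does this automatically.
#'
#' @param gray `H x W` matrix in native units
#' @param smooth_sigma Gaussian smoothing sigma in pixels (default 2)
#' @param min_seed_distance minimum separation between watershed seeds in
#'   pixels (default 7)
#' @param dtype_max dtype ceiling used to normalise before thresholding
#' @param threshold foreground threshold in native intensity units,
#'   applied to the smoothed image; `NULL` (default) computes Otsu's
#'   threshold from the input
#' @return label matrix of the same shape (empty when nothing is above
#'   threshold)
#' @export
baseline_segment <- function(gray, smooth_sigma = 2, min_seed_distance = 7L,
                             dtype_max = 255, threshold = NULL) {
  if (length(gray) == 0L) stop("empty image")
  g <- gray / dtype_max
  empty <- matrix(0L, nrow(gray), ncol(gray))
  if (is.null(threshold) && diff(range(g)) == 0)
    return(empty)   # constant image: no objects
  radius <- 2L * ceiling(3 * smooth_sigma) + 1L
  sm <- if (min(dim(g)) > radius) EBImage::gblur(g, sigma = smooth_sigma) else g
  th <- if (is.null(threshold)) EBImage::otsu(sm, range = range(sm))
        else threshold / dtype_max
  fg <- sm > th
  if (!any(fg)) return(empty)
  d <- EBImage::distmap(fg)
  labels <- EBImage::watershed(d, tolerance = 1, ext = min_seed_distance)
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  labels
}

#' Segmentation backend contract
#'
#' Downstream stages are agnostic to how nuclei were found: a backend is a
#' list with a `name` and a `segment(gray)` function returning a label
#' matrix of the same shape, with ids local to the tile. The shipped
#' `"baseline"` backend wraps [baseline_segment]. To plug in a trained
#' model (e.g. an instance-segmentation network served out of process),
#' supply any function with the same signature — typically a wrapper that
#' writes the tile, invokes the model and reads back the label mask.
#'
#' @param name `"baseline"`, or a function `(gray) -> label matrix` to wrap
#' @param smooth_sigma,min_seed_distance,dtype_max,threshold parameters
#'   forwarded to [baseline_segment] when `name == "baseline"`
#' @return a `segmenter_backend` list with fields `name` and `segment`
#' @export
segmenter_backend <- function(name = "baseline", smooth_sigma = 2,
                              min_seed_distance = 7L, dtype_max = 255,
                              threshold = NULL) {
  if (is.function(name)) {
    return(structure(list(name = "custom", segment = name),
                     class = "segmenter_backend"))
  }
  if (!identical(name, "baseline"))
    stop("unknown backend: ", name)
  structure(list(
    name = "baseline",
    segment = function(gray) {
      baseline_segment(gray, smooth_sigma = smooth_sigma,
                       min_seed_distance = min_seed_distance,
                       dtype_max = dtype_max, threshold = threshold)
    }
  ), class = "segmenter_backend")
}

#' Shared foreground threshold for tiled segmentation
#'
#' Otsu's threshold of the smoothed full image, in native intensity
#' units. Passing this to [baseline_segment] (or building a
#' [segmenter_backend] with it) makes every tile cut foreground at the
#' same level, so the tiled-and-stitched segmentation reproduces the
#' un-tiled one.
#'
#' @inheritParams baseline_segment
#' @return scalar threshold in native units
#' @export
global_threshold <- function(gray, smooth_sigma = 2, dtype_max = 255) {
  g <- gray / dtype_max
  if (diff(range(g)) == 0) return(dtype_max)  # constant: nothing above
  sm <- EBImage::gblur(g, sigma = smooth_sigma)
  EBImage::otsu(sm, range = range(sm)) * dtype_max
}

#' Stitch per-tile segmentations into one label image
#'
#' Every mask whose centroid (in parent coordinates) falls inside its
#' tile's core region is kept; masks outside are duplicates that another
#' tile owns. Core regions partition the image and ownership of a centroid
#' on a shared core edge is resolved half-open (toward the earlier tile),
#' so each object is kept by exactly one tile. Kept masks are copied to
#' the parent grid and relabelled with consecutive ids in raster order of
#' their centroids. When two tiles both keep a borderline object the
#' conflicting pixels go to the mask with the nearer centroid, with a
#' warning.
#'
#' @param tile_labels list of `list(tile = <image_tile>, labels = <label
#'   matrix>)` pairs from one [tile_image] call
#' @param parent_dim `c(H, W)` of the parent image; inferred from the tile
#'   layout when omitted
#' @return label matrix for the full image
#' @export
stitch_tiles <- function(tile_labels, parent_dim = NULL) {
  stopifnot(length(tile_labels) >= 1L)
  if (is.null(parent_dim)) {
    H <- max(vapply(tile_labels, function(tl)
      tl$tile$row_off + nrow(tl$tile$pixels), numeric(1)))
    W <- max(vapply(tile_labels, function(tl)
      tl$tile$col_off + ncol(tl$tile$pixels), numeric(1)))
    parent_dim <- c(H, W)
  }
  H <- parent_dim[1]; W <- parent_dim[2]

  kept <- list()
  for (tl in tile_labels) {
    tile <- tl$tile; labs <- tl$labels
    if (!all(dim(labs) == dim(tile$pixels)))
      stop("tile labels do not match tile shape")
    cen <- label_centroids(labs)
    if (nrow(cen) == 0L) next
    cr <- cen$row + tile$row_off   # parent coordinates
    cc <- cen$col + tile$col_off
    core <- tile$core
    # half-open continuous ownership: [r0 - 0.5, r1 + 0.5)
    own <- cr >= core[1] - 0.5 & cr < core[2] + 0.5 &
           cc >= core[3] - 0.5 & cc < core[4] + 0.5
    th <- nrow(labs)
    for (k in which(own)) {
      idx <- which(labs == cen$id[k])
      r <- ((idx - 1L) %% th) + 1L + tile$row_off
      c <- ((idx - 1L) %/% th) + 1L + tile$col_off
      kept[[length(kept) + 1L]] <- list(
        pix = (c - 1L) * H + r, row = cr[k], col = cc[k])
    }
  }
  out <- matrix(0L, H, W)
  if (length(kept) == 0L) return(out)
  ord <- order(vapply(kept, `[[`, numeric(1), "row"),
               vapply(kept, `[[`, numeric(1), "col"))
  kept <- kept[ord]
  src <- vector("list", length(kept))   # claimant per painted pixel
  warned <- FALSE
  for (newid in seq_along(kept)) {
    m <- kept[[newid]]
    free <- out[m$pix] == 0L
    if (!all(free)) {
      if (!warned) {
        warning("overlapping masks kept by different tiles; ",
                "conflicting pixels assigned by nearer centroid")
        warned <- TRUE
      }
      clash <- m$pix[!free]
      r <- ((clash - 1L) %% H) + 1L
      c <- ((clash - 1L) %/% H) + 1L
      other <- out[clash]
      d_new <- (r - m$row)^2 + (c - m$col)^2
      d_old <- (r - vapply(kept[other], `[[`, numeric(1), "row"))^2 +
               (c - vapply(kept[other], `[[`, numeric(1), "col"))^2
      take <- clash[d_new < d_old]
      out[take] <- newid
    }
    out[m$pix[free]] <- newid
  }
  out
}

#' Remove artifact objects below a size threshold
#'
#' Erroneously segmented imaging artifacts typically appear as small
#' high-intensity speckles; objects with strictly fewer than `min_area`
#' pixels are set to background. Surviving objects keep their ids. The
#' operation is idempotent and monotone in `min_area`.
#'
#' @param labels label matrix
#' @param min_area minimum object area in pixels (objects with area
#'   `< min_area` are removed); 0 is the identity
#' @return filtered label matrix
#' @export
filter_small_objects <- function(labels, min_area) {
  validate_label_image(labels)
  if (min_area < 0) stop("`min_area` must be >= 0")
  if (min_area == 0L) return(labels)
  mx <- max(labels)
  if (mx == 0L) return(labels)
  areas <- tabulate(labels[labels > 0L], nbins = mx)
  drop <- which(areas > 0L & areas < min_area)
  if (length(drop)) labels[labels %in% drop] <- 0L
  labels
}
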