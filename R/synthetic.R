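# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic fluorescence nuclear image with ground truth
#'
#' Emulates a nuclear-stain channel: bright, roughly elliptical nuclei of
#' varying size, eccentricity and brightness on a dark background with
#' additive Gaussian noise. Nuclei are placed by rejection sampling so
#' that any two are separated by at least `min_gap` background pixels
#' (Chebyshev separation `> min_gap`); when 10,000 placement attempts are
#' exhausted the scene is returned with fewer cells and a warning. Fixed
#' `seed` and parameters give a bit-identical scene.
#'
#' @param n_cells number of nuclei requested
#' @param height,width image size in pixels
#' @param radius_range semi-minor axis range in pixels (default 4--12)
#' @param ecc_range axis-ratio (semi-major / semi-minor) range
#'   (default 1--2.5)
#' @param min_gap minimum background gap between nuclei in pixels
#' @param noise_sd additive Gaussian noise standard deviation in intensity
#'   units (default 8 on the 8-bit scale)
#' @param seed RNG seed
#' @param bg_level background intensity (default 20)
#' @param intensity_range per-nucleus interior brightness range
#'   (default 150--240)
#' @param dtype_max intensity ceiling (default 255)
#' @return list with `image` (a single-channel [multichannel_image] named
#'   `"nuclear"`), `labels` (ground-truth label matrix) and `params`
#' @export
generate_nuclei <- function(n_cells, height, width,
                            radius_range = c(4, 12),
                            ecc_range = c(1.0, 2.5),
                            min_gap = 2L, noise_sd = 8, seed = 0L,
                            bg_level = 20, intensity_range = c(150, 240),
                            dtype_max = 255) {
  if (height < 1 || width < 1) stop("image area must be positive")
  stopifnot(n_cells >= 0, min_gap >= 0, noise_sd >= 0)
  params <- list(n_cells = n_cells, height = height, width = width,
                 radius_range = radius_range, ecc_range = ecc_range,
                 min_gap = min_gap, noise_sd = noise_sd, seed = seed)
  with_seed(seed, {
    labels <- matrix(0L, height, width)
    blocked <- matrix(FALSE, height, width)
    placed <- 0L; tries <- 0L
    while (placed < n_cells && tries < 10000L) {
      tries <- tries + 1L
      b <- stats::runif(1, radius_range[1], radius_range[2])
      a <- b * stats::runif(1, ecc_range[1], ecc_range[2])
      theta <- stats::runif(1, 0, pi)
      margin <- ceiling(a) + 1
      if (2 * margin >= height || 2 * margin >= width) next
      cy <- stats::runif(1, margin, height - margin)
      cx <- stats::runif(1, margin, width - margin)
      ext <- ceiling(a)
      rr <- max(1L, floor(cy - ext)):min(height, ceiling(cy + ext))
      cc <- max(1L, floor(cx - ext)):min(width, ceiling(cx + ext))
      dy <- outer(rr - cy, rep(1, length(cc)))
      dx <- outer(rep(1, length(rr)), cc - cx)
      u <- dx * cos(theta) + dy * sin(theta)
      v <- -dx * sin(theta) + dy * cos(theta)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      if (!any(inside)) next
      if (any(blocked[rr, cc][inside])) next
      if (any(labels[rr, cc][inside] > 0L)) next
      placed <- placed + 1L
      sub <- labels[rr, cc]; sub[inside] <- placed; labels[rr, cc] <- sub
      # block a Chebyshev-`min_gap` halo around the new nucleus
      for (dr in -min_gap:min_gap) for (dc in -min_gap:min_gap) {
        r2 <- rr + dr; c2 <- cc + dc
        ok_r <- r2 >= 1L & r2 <= height; ok_c <- c2 >= 1L & c2 <= width
        sb <- blocked[r2[ok_r], c2[ok_c], drop = FALSE]
        sb[inside[ok_r, ok_c, drop = FALSE]] <- TRUE
        blocked[r2[ok_r], c2[ok_c]] <- sb
      }
    }
    if (placed < n_cells)
      warning("placed only ", placed, " of ", n_cells,
              " nuclei within the attempt budget")
    img <- matrix(bg_level, height, width)
    if (placed > 0L) {
      bright <- stats::runif(placed, intensity_range[1], intensity_range[2])
      fg <- labels > 0L
      img[fg] <- bright[labels[fg]]
    }
    img <- img + stats::rnorm(length(img), sd = noise_sd)
    img <- pmin(pmax(img, 0), dtype_max)
    list(image = multichannel_image(img, channel_names = "nuclear",
                                    dtype_max = dtype_max),
         labels = labels, params = params)
  })
}

#' Render multi-channel marker images with known lateral spillover
#'
#' Builds a full synthetic scene for testing bleed compensation end to
#' end. Each cell is assigned exactly one marker of each mutually
#' exclusive pair (its true level drawn from `high_range`, the partner
#' 0). The ground-truth labels are expanded by `grow_pixels`, the contact
#' matrix of the expanded labels is computed with [contact_ratios] — the
#' very matrix [compensate] later inverts — and the observed per-cell
#' means are set to `A %*% true_signal`. Each cell's expanded mask is
#' painted uniformly with its observed value, plus pixelwise Gaussian
#' noise over the whole image.
#'
#' @param gt_labels ground-truth nucleus label matrix with at least 2
#'   cells (e.g. from [generate_nuclei])
#' @param n_channels number of marker channels (default 4)
#' @param exclusive_pairs list of channel-index pairs that are
#'   biologically mutually exclusive (default `(1,2)` and `(3,4)`)
#' @param grow_pixels mask expansion applied before computing contacts
#' @param seed RNG seed
#' @param noise_sd pixelwise Gaussian noise sd (default 2)
#' @param high_range range of the true positive-marker level
#'   (default 80--120)
#' @param dtype_max intensity ceiling
#' @return a `synthetic_scene`: list with `image` (the marker
#'   [multichannel_image]), `gt_labels`, `expanded_labels`, `true_signal`
#'   (`n x C`, rownames = cell ids), `contacts` and `params`
#' @export
render_spillover_channels <- function(gt_labels, n_channels = 4L,
                                      exclusive_pairs = list(c(1L, 2L),
                                                             c(3L, 4L)),
                                      grow_pixels = 2L, seed = 0L,
                                      noise_sd = 2, high_range = c(80, 120),
                                      dtype_max = 255) {
  validate_label_image(gt_labels)
  ids <- label_ids(gt_labels)
  n <- length(ids)
  if (n < 2L) stop("at least 2 cells are required")
  for (p in exclusive_pairs)
    stopifnot(length(p) == 2L, all(p >= 1L), all(p <= n_channels))
  channel_names <- paste0("marker", seq_len(n_channels))
  with_seed(seed, {
    s <- matrix(0, n, n_channels, dimnames = list(ids, channel_names))
    for (p in exclusive_pairs) {
      pick_first <- stats::runif(n) < 0.5
      level <- stats::runif(n, high_range[1], high_range[2])
      s[cbind(seq_len(n), ifelse(pick_first, p[1], p[2]))] <- level
    }
    expanded <- expand_masks_nearest_center(gt_labels, grow_pixels)
    contacts <- contact_ratios(expanded)
    stopifnot(identical(contacts$ids, ids))
    observed <- contacts$A %*% s
    H <- nrow(gt_labels); W <- ncol(gt_labels)
    pix <- array(0, dim = c(H, W, n_channels))
    idxmap <- match(as.integer(expanded), c(0L, ids)) - 1L  # 0 = background
    fg <- which(idxmap > 0L)
    for (k in seq_len(n_channels)) {
      plane <- matrix(0, H, W)
      plane[fg] <- observed[idxmap[fg], k]
      pix[, , k] <- plane
    }
    pix <- pix + stats::rnorm(length(pix), sd = noise_sd)
    pix <- pmin(pmax(pix, 0), dtype_max)
    structure(list(
      image = multichannel_image(pix, channel_names = channel_names,
                                 dtype_max = dtype_max),
      gt_labels = gt_labels, expanded_labels = expanded,
      true_signal = s, contacts = contacts,
      params = list(n_channels = n_channels,
                    exclusive_pairs = exclusive_pairs,
                    grow_pixels = grow_pixels, seed = seed,
                    noise_sd = noise_sd, high_range = high_range)
    ), class = "synthetic_scene")
  })
}
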