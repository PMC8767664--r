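#' Per-cell statistics from a segmentation
#'
#' Builds the cell table: for each cell, the centroid and pixel count of
#' its nucleus mask and the mean intensity of every channel over its
#' (possibly expanded) quantification mask. The nucleus mask defines
#' location and size; the expanded mask defines the pixels quantified, so
#' membrane-localised signal captured by expansion enters the means.
#' Means are computed in double precision.
#'
#' @param nuclei label matrix of nucleus masks
#' @param expanded label matrix of quantification masks; must share ids
#'   with `nuclei` and contain each nucleus (`expanded` is a per-id
#'   superset). Pass `nuclei` again to quantify without expansion.
#' @param image a [multichannel_image] of the same height and width
#' @return a `cell_table`: data.frame sorted by cell id with columns
#'   `cell_id`, `x`, `y` (0-based nucleus centroid, `x` = column,
#'   `y` = row), `size` (nucleus pixel count) and one raw-mean column per
#'   channel, named by channel. Channel names are kept in
#'   `attr(, "channels")`.
#' @export
quantify_cells <- function(nuclei, expanded, image) {
  stopifnot(inherits(image, "multichannel_image"))
  validate_label_image(nuclei)
  validate_label_image(expanded)
  d <- dim(image$pixels)
  if (!all(dim(nuclei) == d[1:2]) || !all(dim(expanded) == d[1:2]))
    stop("label images must match the image height and width")
  nid <- label_ids(nuclei); eid <- label_ids(expanded)
  if (length(setdiff(eid, nid)))
    stop("expanded labels contain ids absent from the nucleus labels: ",
         paste(setdiff(eid, nid), collapse = ", "))
  fgn <- nuclei > 0L
  if (any(expanded[fgn] != nuclei[fgn]))
    stop("expanded masks must contain their nucleus masks")
  channels <- image$channel_names
  if (length(nid) == 0L) {
    tab <- data.frame(cell_id = integer(), x = numeric(), y = numeric(),
                      size = integer())
    for (ch in channels) tab[[ch]] <- numeric()
    return(structure(tab, channels = channels, class = c("cell_table",
                                                         "data.frame")))
  }
  cen <- label_centroids(nuclei)
  size <- tabulate(nuclei[fgn], nbins = max(nid))[nid]

  fge <- which(expanded > 0L)
  gid <- as.integer(expanded[fge])
  counts <- tabulate(gid, nbins = max(nid))[nid]
  tab <- data.frame(cell_id = nid, x = cen$col - 1, y = cen$row - 1,
                    size = as.integer(size))
  for (k in seq_along(channels)) {
    ch <- image$pixels[, , k]
    sums <- rowsum(as.numeric(ch[fge]), gid)
    means <- numeric(length(nid))
    means[match(as.integer(rownames(sums)), nid)] <- sums[, 1]
    tab[[channels[k]]] <- means / counts
  }
  structure(tab, channels = channels, class = c("cell_table", "data.frame"))
}
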