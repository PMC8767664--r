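#' Read a microscopy image (TIFF, PNG or JPEG)
#'
#' Multi-page TIFFs map pages to channels; RGB PNG/JPEG maps colour planes
#' to channels; grayscale maps to a single channel. Pixel values are
#' returned in native integer units together with the dtype ceiling
#' (255 for 8-bit, 65535 for 16-bit sources).
#'
#' @param path path to a `.tif`/`.tiff`, `.png`, `.jpg`/`.jpeg` file
#' @param channel_names optional character vector overriding the default
#'   `"ch0" .. "ch{C-1}"` names (e.g. marker names for a multi-page TIFF,
#'   which carries none of its own)
#' @return a [multichannel_image]
#' @export
read_image <- function(path, channel_names = NULL) {
  if (!file.exists(path)) stop("cannot read image, file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e) stop("not a readable TIFF: ", path))
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) == 1L && length(dim(pages[[1]])) == 3L) {
      arr <- pages[[1]]  # single RGB(A) page: planes become channels
    } else {
      pages <- lapply(pages, function(p) {
        if (length(dim(p)) == 3L) p[, , 1] else p  # flatten odd RGB pages
      })
      arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    }
    dmax <- if (max(arr) > 255) 65535 else 255
  } else if (ext == "png") {
    arr <- tryCatch(png::readPNG(path),
                    error = function(e) stop("not a readable PNG: ", path))
    depth <- png_bit_depth(path)
    dmax <- 2^depth - 1
    arr <- round(arr * dmax)
  } else if (ext %in% c("jpg", "jpeg")) {
    arr <- tryCatch(jpeg::readJPEG(path),
                    error = function(e) stop("not a readable JPEG: ", path))
    dmax <- 255
    arr <- round(arr * dmax)
  } else {
    stop("unsupported image format '", ext, "': ", path)
  }
  if (is.matrix(arr)) dim(arr) <- c(dim(arr), 1L)
  multichannel_image(arr, channel_names = channel_names, dtype_max = dmax)
}

# Bit depth from the PNG IHDR chunk (byte 25 of the file).
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) return(8L)
  as.integer(hdr[25L])
}

#' Write a cell table as CSV or FCS
#'
#' CSV: one header row, then one row per cell with columns `cell_id`, `x`,
#' `y`, `size`, one column per channel of raw means and, when compensation
#' ran, one `<channel>_comp` column per channel. FCS: one event per cell;
#' parameters are `x`, `y`, `size` and the per-channel means, stored as
#' 32-bit floats (FCS 3.1 list mode).
#'
#' @param table a `cell_table` (see [quantify_cells])
#' @param path output file path
#' @param format `"csv"` or `"fcs"`
#' @export
write_cell_table <- function(table, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  } else {
    cols <- setdiff(names(table), "cell_id")
    dat <- as.matrix(as.data.frame(table)[, cols, drop = FALSE])
    write_fcs(dat, path)
  }
  invisible(path)
}

# Minimal FCS 3.1 writer: single dataset, list-mode 32-bit floats,
# little-endian, required keywords only.
write_fcs <- function(data, path) {
  data <- as.matrix(data)
  npar <- ncol(data); ntot <- nrow(data)
  pnames <- colnames(data)
  if (is.null(pnames)) pnames <- paste0("P", seq_len(npar))
  pmax_r <- vapply(seq_len(npar), function(j) {
    m <- if (ntot > 0) max(data[, j]) else 0
    max(1, ceiling(m))
  }, numeric(1))
  delim <- "/"
  kw <- c(
    "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
    "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
    "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
    "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
    "$NEXTDATA", "0",
    "$PAR", as.character(npar), "$TOT", as.character(ntot)
  )
  for (j in seq_len(npar)) {
    kw <- c(kw,
            sprintf("$P%dN", j), pnames[j],
            sprintf("$P%dB", j), "32",
            sprintf("$P%dE", j), "0,0",
            sprintf("$P%dR", j), format(pmax_r[j], scientific = FALSE))
  }
  make_text <- function() {
    paste0(delim, paste(gsub(delim, " ", kw, fixed = TRUE), collapse = delim),
           delim)
  }
  # data offsets depend on TEXT length; zero-padded widths make this stable
  kw[kw == "%BD%"] <- sprintf("%010d", 0)
  kw[kw == "%ED%"] <- sprintf("%010d", 0)
  text_len <- nchar(make_text(), type = "bytes")
  data_begin <- 58L + text_len
  data_end <- if (ntot > 0) data_begin + 4L * npar * ntot - 1L else 0L
  kw[which(kw == "$BEGINDATA") + 1L] <- sprintf("%010d", data_begin)
  kw[which(kw == "$ENDDATA") + 1L] <- sprintf("%010d", data_end)
  text <- make_text()
  stopifnot(nchar(text, type = "bytes") == text_len)
  text_begin <- 58L; text_end <- 58L + text_len - 1L
  off <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.1    ", off(text_begin), off(text_end),
                   off(data_begin), off(if (ntot > 0) data_end else 0L),
                   off(0L), off(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (ntot > 0)
    writeBin(as.numeric(t(data)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Export per-cell mask ROIs as a multi-page TIFF stack
#'
#' Page `k` is the binary mask of the `k`-th cell id in ascending order;
#' the page count equals the number of distinct non-zero labels. With an
#' all-background labelling nothing is written and a warning is raised.
#'
#' @param labels label matrix
#' @param path output TIFF path
#' @return invisibly, the number of pages written
#' @export
export_roi_stack <- function(labels, path) {
  validate_label_image(labels)
  ids <- label_ids(labels)
  if (length(ids) == 0L) {
    warning("no objects in label image; ROI stack not written: ", path)
    return(invisible(0L))
  }
  pages <- lapply(ids, function(id) (labels == id) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(length(ids))
}

#' Write a label image as a 16-bit TIFF
#' @param labels label matrix (ids must be < 65536)
#' @param path output path
#' @export
write_label_tiff <- function(labels, path) {
  validate_label_image(labels)
  if (max(labels) > 65535L) stop("label ids exceed 16-bit range")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label image from a TIFF
#'
#' Accepts either a single-page integer label TIFF (as written by
#' [write_label_tiff]) or a multi-page ROI stack (as written by
#' [export_roi_stack]), in which case page `k` becomes cell id `k`.
#'
#' @param path TIFF path
#' @return label matrix
#' @export
read_label_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  if (length(pages) == 1L) {
    labels <- pages[[1]]
    storage.mode(labels) <- "integer"
    return(labels)
  }
  labels <- matrix(0L, nrow(pages[[1]]), ncol(pages[[1]]))
  for (k in seq_along(pages)) labels[pages[[k]] > 0] <- k
  labels
}

#' Render a channel with mask outlines
#'
#' Returns an RGB rendering (`H x W x 3`, values in `[0, 1]`) of the chosen
#' channel with 1-pixel mask outlines drawn in a contrasting colour. Outline
#' pixels are exactly the mask boundary pixels under the 4-neighbour rule
#' (a mask pixel with a 4-neighbour of different label or background).
#'
#' @param image a [multichannel_image]
#' @param labels label matrix of the same height and width
#' @param channel channel index or name to render as grayscale
#' @param color length-3 RGB vector in `[0, 1]` for the outlines
#' @return `H x W x 3` numeric array in `[0, 1]`
#' @export
render_overlay <- function(image, labels, channel = 1, color = c(1, 0, 0)) {
  stopifnot(inherits(image, "multichannel_image"))
  validate_label_image(labels)
  d <- dim(image$pixels)
  if (!all(dim(labels) == d[1:2]))
    stop("label image dimensions do not match the image")
  gray <- get_channel(image, channel) / image$dtype_max
  rgb <- array(rep(gray, 3L), dim = c(d[1], d[2], 3L))
  outline <- label_boundary(labels)
  for (k in 1:3) {
    plane <- rgb[, , k]
    plane[outline] <- color[k]
    rgb[, , k] <- plane
  }
  rgb
}

#' Write an RGB overlay to PNG
#' @param rgb `H x W x 3` array in `[0, 1]` (from [render_overlay])
#' @param path output PNG path
#' @export
write_overlay_png <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}
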