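# Rec. 601 luma weights for RGB -> gray collapse (rounded to nearest level)
.LUMA <- c(0.299, 0.587, 0.114)

#' Read a grayscale micrograph
#'
#' Reads an 8- or 16-bit single-channel or RGB TIFF/PNG and normalizes it to
#' the package's canonical [GrayImage-class] representation (integer levels).
#' RGB input is collapsed to luminance with the Rec. 601 weights, rounded to
#' the nearest integer level; an alpha channel, if present, is dropped.
#'
#' @param path path to a TIFF or PNG file.
#' @param pixelSize optional physical pixel size (nm/px) to record.
#' @return A [GrayImage-class].
#' @examples
#' p <- tempfile(fileext = ".png")
#' writeGrayImage(grayImage(matrix(128L, 16, 16)), p)
#' readGrayImage(p)
#' @export
readGrayImage <- function(path, pixelSize = NA_real_) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
    if (length(pages) > 1L)
      stop(sprintf("multi-page TIFF not supported (%d pages): %s",
                   length(pages), path))
    raw <- pages[[1L]]
    bitdepth <- if (max(raw) > 255) 16L else {
      bps <- attr(raw, "bits.per.sample")
      if (!is.null(bps) && bps[1] == 16) 16L else 8L
    }
  } else if (ext == "png") {
    raw <- png::readPNG(path)
    # readPNG scales to [0,1]; recover the level set (16-bit unless every
    # value sits exactly on the 8-bit grid)
    on255 <- max(abs(raw * 255 - round(raw * 255))) < 1e-9
    bitdepth <- if (on255) 8L else 16L
    raw <- raw * (2^bitdepth - 1)
  } else {
    stop("unsupported image format '", ext, "': use TIFF or PNG")
  }
  px <- .collapseChannels(raw)
  px <- round(px)
  storage.mode(px) <- "integer"
  grayImage(px, bitdepth = bitdepth, pixelSize = pixelSize)
}

.collapseChannels <- function(raw) {
  if (length(dim(raw)) == 2L) return(raw)
  nc <- dim(raw)[3]
  if (nc == 2L) return(raw[, , 1L])                      # gray + alpha
  if (nc %in% c(3L, 4L))                                 # RGB(A) -> luma
    return(.LUMA[1] * raw[, , 1] + .LUMA[2] * raw[, , 2] +
           .LUMA[3] * raw[, , 3])
  stop("unsupported channel count: ", nc)
}

#' Write a grayscale image or binary mask
#'
#' Lossless output. [GrayImage-class] objects keep their bit depth (16-bit
#' requires TIFF; PNG output is 8-bit). Binary masks (a
#' [SegmentationResult-class] or a 0/1 matrix) are written as 8-bit
#' \{0, 255\}.
#'
#' @param x a [GrayImage-class], [SegmentationResult-class], or 0/1 matrix.
#' @param path output path ending in .png, .tif or .tiff.
#' @return Invisibly, \code{path}.
#' @export
writeGrayImage <- function(x, path) {
  if (!dir.exists(dirname(path)))
    stop("cannot write image: no such directory: ", dirname(path))
  if (is(x, "SegmentationResult")) x <- segMask(x)
  if (is.matrix(x) && all(x %in% c(0, 1)))
    x <- grayImage(matrix(as.integer(x) * 255L, nrow(x), ncol(x)),
                   bitdepth = 8L)
  if (!is(x, "GrayImage"))
    stop("x must be a GrayImage, SegmentationResult or binary matrix")
  ext <- tolower(tools::file_ext(path))
  L1 <- 2^bitDepth(x) - 1
  scaled <- pixels(x) / L1
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = bitDepth(x),
                    compression = "none")
  } else if (ext == "png") {
    if (bitDepth(x) == 16L)
      stop("16-bit PNG output not supported; write a TIFF instead")
    png::writePNG(scaled, path)
  } else {
    stop("unsupported output format '", ext, "': use TIFF or PNG")
  }
  invisible(path)
}

#' Write per-component contours as CSV
#'
#' One row per contour pixel: \code{component_id, x, y} with 0-based pixel
#' coordinates, \code{x} = column, \code{y} = row.
#'
#' @param result a [SegmentationResult-class] with contours extracted.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeContours <- function(result, path) {
  ct <- segContours(result)
  if (!length(ct)) stop("no contours in result; run extractContours() first")
  rows <- do.call(rbind, lapply(seq_along(ct), function(i) {
    cbind(component_id = i, ct[[i]])
  }))
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE)
  invisible(path)
}

#' Write per-component statistics as CSV
#'
#' Columns: id, area (px), centroid_x, centroid_y (0-based), and
#' equivalent_diameter (px, diameter of the equal-area disk).
#'
#' @param result a [SegmentationResult-class].
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeComponentStats <- function(result, path) {
  lab <- segLabels(result)
  n <- nComponents(result)
  stats <- data.frame(id = seq_len(n), area = componentAreas(result),
                      centroid_x = NA_real_, centroid_y = NA_real_)
  if (n) {
    idx <- which(lab > 0L, arr.ind = TRUE)
    l <- lab[lab > 0L]
    stats$centroid_y <- tapply(idx[, 1] - 1, l, mean)[as.character(stats$id)]
    stats$centroid_x <- tapply(idx[, 2] - 1, l, mean)[as.character(stats$id)]
  }
  stats$equivalent_diameter <- 2 * sqrt(stats$area / pi)
  utils::write.csv(stats, path, row.names = FALSE)
  invisible(path)
}
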