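#' Binarize an image at a threshold
#'
#' Dark polarity (the bright-field TEM default: particles scatter/absorb and
#' appear dark) marks pixels strictly below the threshold; bright polarity
#' marks pixels strictly above it.
#'
#' @param img a [GrayImage-class].
#' @param t threshold level.
#' @param polarity \code{"dark"} or \code{"bright"}.
#' @return Integer 0/1 matrix (1 = particle).
#' @export
binarize <- function(img, t, polarity = c("dark", "bright")) {
  stopifnot(is(img, "GrayImage"))
  polarity <- match.arg(polarity)
  m <- if (polarity == "dark") pixels(img) < t else pixels(img) > t
  storage.mode(m) <- "integer"
  m
}

#' Clean up a binary mask
#'
#' Removes components smaller than \code{minArea} (and, optionally, larger
#' than \code{maxArea}), optionally fills enclosed holes, and optionally
#' applies the size-convexity constraint: components whose pixel area divided
#' by their convex hull area falls below \code{convexityMin} are removed.
#' The convexity filter rejects curvilinear structures (membranes, synapses)
#' whose hull is far larger than the structure itself, while compact
#' particles have convexity near 1. Hole filling defaults off because pores
#' between aggregated particles are real structure worth preserving.
#' Idempotent: applying the same post-processing twice equals applying it
#' once.
#'
#' @param mask integer 0/1 matrix.
#' @param minArea minimum component area in pixels (components strictly
#'   smaller are removed).
#' @param fillHoles fill background holes enclosed by foreground.
#' @param convexityMin optional minimum area / convex-hull-area ratio.
#' @param maxArea optional maximum component area in pixels.
#' @return Cleaned integer 0/1 matrix.
#' @export
postprocessMask <- function(mask, minArea = 9L, fillHoles = FALSE,
                            convexityMin = NULL, maxArea = NULL) {
  stopifnot(is.matrix(mask), all(mask %in% c(0L, 1L)))
  if (minArea < 0) stop("minArea must be >= 0")
  if (fillHoles) {
    filled <- EBImage::fillHull(EBImage::Image(mask))
    mask <- EBImage::imageData(filled)
    storage.mode(mask) <- "integer"
  }
  lab <- .label8_cpp(mask)
  n <- max(lab)
  if (n == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  drop <- areas < minArea
  if (!is.null(maxArea)) drop <- drop | areas > maxArea
  if (!is.null(convexityMin)) {
    conv <- .componentConvexity(lab, n)
    drop <- drop | conv < convexityMin
  }
  if (any(drop)) {
    mask[lab %in% which(drop)] <- 0L
  }
  mask
}

# area / convex hull area per component; hull pixel area approximated by
# Pick's theorem (interior + boundary lattice points of the hull polygon)
.componentConvexity <- function(lab, n) {
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  split_idx <- split(seq_along(l), l)
  vapply(as.character(seq_len(n)), function(k) {
    rows <- idx[split_idx[[k]], , drop = FALSE]
    a <- nrow(rows)
    if (a < 3L) return(1)
    h <- grDevices::chull(rows[, 2], rows[, 1])
    hx <- rows[h, 2]; hy <- rows[h, 1]
    m <- length(h)
    if (m < 3L) return(1)
    nx <- c(hx[-1L], hx[1L]); ny <- c(hy[-1L], hy[1L])
    polyA <- abs(sum(hx * ny - nx * hy)) / 2
    boundary <- sum(mapply(function(dx, dy) {
      if (dx == 0 && dy == 0) 0 else .gcd(abs(dx), abs(dy))
    }, nx - hx, ny - hy))
    hullPix <- polyA + boundary / 2 + 1
    min(1, a / hullPix)
  }, numeric(1))
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Label connected components of a mask
#'
#' 8-connectivity labeling (diagonally touching pixels belong to one
#' component), with labels assigned deterministically in scan order.
#'
#' @param mask integer 0/1 matrix.
#' @return A [SegmentationResult-class] with mask, labels, component count
#'   and areas (contours empty until [extractContours()]).
#' @export
labelComponents <- function(mask) {
  stopifnot(is.matrix(mask), all(mask %in% c(0L, 1L)))
  storage.mode(mask) <- "integer"
  lab <- .label8_cpp(mask)
  n <- max(lab)
  areas <- if (n) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  new("SegmentationResult", mask = mask, labels = lab,
      nComponents = as.integer(n), areas = as.integer(areas))
}

#' Extract per-component contours
#'
#' The default \code{boundary} method traces each component's outer boundary
#' (an ordered, closed chain of 8-connected boundary pixels), which is
#' deterministic. The \code{canny} method runs Canny edge detection on the
#' masked intensity image (or on the mask itself when no image is given) and
#' assigns edge pixels to components. Contours are reported with columns
#' \code{x} (column) and \code{y} (row), 0-based, ordered counter-clockwise
#' in the image frame (x right, y down).
#'
#' @param result a [SegmentationResult-class].
#' @param method \code{"boundary"} or \code{"canny"}.
#' @param img optional [GrayImage-class] for Canny on grayscale data.
#' @return The result with \code{contours} populated.
#' @export
extractContours <- function(result, method = c("boundary", "canny"),
                            img = NULL) {
  stopifnot(is(result, "SegmentationResult"))
  method <- match.arg(method)
  n <- nComponents(result)
  if (n == 0L) return(initialize(result, contours = list()))
  if (method == "boundary") {
    oc <- EBImage::ocontour(EBImage::Image(result@labels))
    contours <- lapply(seq_len(n), function(k) {
      m <- oc[[k]]                       # 0-based (row, col)
      xy <- cbind(x = m[, 2L], y = m[, 1L])
      .orientCCW(xy)
    })
  } else {
    src <- if (is.null(img)) {
      grayImage(result@mask * 255L, bitdepth = 8L)
    } else {
      px <- pixels(img)
      px[result@mask == 0L] <- as.integer(2^bitDepth(img) - 1)
      grayImage(px, bitdepth = bitDepth(img))
    }
    edges <- cannyEdges(src)
    # attach each edge pixel to the nearest labeled component (edges sit on
    # the mask boundary, so a 1-px dilation of the labels covers them)
    labd <- .dilateLabels(result@labels)
    idx <- which(edges == 1L & labd > 0L, arr.ind = TRUE)
    comp <- labd[cbind(idx[, 1], idx[, 2])]
    contours <- lapply(seq_len(n), function(k) {
      rows <- idx[comp == k, , drop = FALSE]
      cbind(x = rows[, 2] - 1L, y = rows[, 1] - 1L)
    })
  }
  initialize(result, contours = contours)
}

# reverse the chain if its signed area is clockwise in the
# (x right, y down) frame
.orientCCW <- function(xy) {
  if (nrow(xy) < 3L) return(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  nx <- c(x[-1L], x[1L]); ny <- c(y[-1L], y[1L])
  if (sum(x * ny - nx * y) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  else xy
}

.dilateLabels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  out <- lab
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- lab[pmin(pmax(seq_len(nr) + dr, 1L), nr),
              pmin(pmax(seq_len(nc) + dc, 1L), nc)]
    fill <- out == 0L & sh > 0L
    out[fill] <- sh[fill]
  }
  out
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, four-direction non-maximum
#' suppression and double-threshold hysteresis (weak edges are kept only
#' when 8-connected to a strong edge). When thresholds are not given, the
#' high threshold is the Otsu value of the gradient-magnitude histogram and
#' the low threshold is half of it.
#'
#' @param img a [GrayImage-class].
#' @param sigma Gaussian smoothing sigma in pixels.
#' @param low,high optional hysteresis thresholds on gradient magnitude.
#' @return Integer 0/1 edge matrix.
#' @export
cannyEdges <- function(img, sigma = 1, low = NULL, high = NULL) {
  stopifnot(is(img, "GrayImage"))
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(pixels(img) + 0.0),
                                          sigma = sigma,
                                          boundary = "replicate"))
  gr <- .convolve2(sm, .SOBEL_R)
  gc <- .convolve2(sm, .SOBEL_C)
  mag <- sqrt(gr^2 + gc^2)
  if (max(mag) == 0) return(matrix(0L, nrow(mag), ncol(mag)))
  if (is.null(high)) {
    q <- pmin(as.integer(round(mag / max(mag) * 255)), 255L)
    high <- (.otsuLevel(tabulate(q + 1L, nbins = 256L))$t / 255) * max(mag)
  }
  if (is.null(low)) low <- high / 2
  # non-maximum suppression: quantize the gradient direction to 0/45/90/135
  # degrees and keep pixels that dominate both neighbors along it
  ang <- atan2(gc, gr)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- as.integer(round(ang / (pi / 4))) %% 4L
  nr <- nrow(mag); nc <- ncol(mag)
  shift <- function(m, dr, dc)
    m[pmin(pmax(seq_len(nr) + dr, 1L), nr),
      pmin(pmax(seq_len(nc) + dc, 1L), nc)]
  # sector 0: gradient along rows -> compare row neighbors, etc.
  nb <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
  keep <- matrix(FALSE, nr, nc)
  for (sct in 0:3) {
    d <- nb[[sct + 1L]]
    a <- shift(mag, d[1], d[2]); b <- shift(mag, -d[1], -d[2])
    sel <- sector == sct & mag >= a & mag >= b
    keep[sel] <- TRUE
  }
  mag[!keep] <- 0
  weak <- mag >= low
  strong <- mag >= high
  if (!any(strong)) return(matrix(0L, nr, nc))
  lab <- .label8_cpp(matrix(as.integer(weak), nr, nc))
  good <- unique(lab[strong])
  edges <- matrix(0L, nr, nc)
  edges[lab %in% good[good > 0L]] <- 1L
  edges
}
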