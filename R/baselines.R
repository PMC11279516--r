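# Otsu's criterion on a level-count vector: argmax over split levels k of the
# between-class variance w1*w2*(mu1-mu2)^2, classes {<= k} vs {> k}. Computed
# with cumulative moments; ties broken by the mean of the tied levels (floor),
# the usual convention for plateaued criteria (e.g. a two-valued image).
.otsuLevel <- function(counts) {
  L <- length(counts)
  lev <- 0:(L - 1L)
  total <- sum(counts)
  w1 <- cumsum(counts) / total
  mu <- cumsum(counts * lev)
  muT <- mu[L] / total
  w2 <- 1 - w1
  crit <- ifelse(w1 > 0 & w2 > 0,
                 (muT * w1 - mu / total)^2 / (w1 * w2), -Inf)
  crit <- crit[-L]                       # t = L-1 leaves the high class empty
  best <- which(crit == max(crit))
  t <- floor(mean(lev[best]))
  list(t = t, criterion = crit)
}

#' Global histogram (Otsu) threshold baseline
#'
#' The conventional single-threshold comparator: Otsu's threshold maximizing
#' the between-class variance of the intensity histogram, with a dark-polarity
#' mask. A global threshold cannot adapt to uneven backgrounds, which is the
#' failure mode the entropy-optimized method is designed to avoid.
#'
#' @param img a [GrayImage-class].
#' @param polarity foreground polarity.
#' @return A list with \code{t} (threshold level) and \code{mask}
#'   (integer 0/1 matrix).
#' @export
histogramThreshold <- function(img, polarity = c("dark", "bright")) {
  stopifnot(is(img, "GrayImage"))
  polarity <- match.arg(polarity)
  px <- pixels(img)
  if (min(px) == max(px)) stop("constant image: histogram threshold undefined")
  counts <- tabulate(as.numeric(px) + 1, nbins = nLevels(img))
  t <- .otsuLevel(counts)$t
  # Otsu splits {<= t} vs {> t}; binarize() uses a strict comparison, so the
  # dark-foreground cut sits at t + 1
  mask <- if (polarity == "dark") binarize(img, t + 1L, "dark")
          else binarize(img, t, "bright")
  list(t = t, mask = mask)
}

#' Local adaptive-mean (dynamic) threshold baseline
#'
#' Per-pixel threshold equal to the Gaussian-weighted local mean over a
#' \code{blockSize} window minus \code{offset}; pixels darker than their
#' local threshold are marked (dark polarity). Adapts to smooth background
#' variation but, by construction, responds to any local contrast, so it
#' marks edges of large background structures as readily as particles.
#'
#' @param img a [GrayImage-class].
#' @param blockSize odd window side length in pixels (>= 3).
#' @param offset intensity-level offset subtracted from the local mean.
#' @param polarity foreground polarity.
#' @return Integer 0/1 mask matrix.
#' @export
dynamicThreshold <- function(img, blockSize = 51L, offset = 5,
                             polarity = c("dark", "bright")) {
  stopifnot(is(img, "GrayImage"))
  polarity <- match.arg(polarity)
  blockSize <- as.integer(blockSize)
  if (blockSize %% 2L == 0L || blockSize < 3L)
    stop("blockSize must be odd and >= 3")
  if (blockSize >= min(dim(img)))
    stop("blockSize must be smaller than the image")
  px <- pixels(img) + 0.0
  brush <- EBImage::makeBrush(blockSize, shape = "gaussian",
                              sigma = blockSize / 6)
  localMean <- .convolve2(px, brush)
  m <- if (polarity == "dark") px < localMean - offset
       else px > localMean + offset
  storage.mode(m) <- "integer"
  m
}
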