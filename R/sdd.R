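# Sobel stencils, normalized so a unit-slope ramp has unit gradient.
# Row kernel differentiates along the first (row) index.
.SOBEL_R <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = FALSE) / 8
.SOBEL_C <- t(.SOBEL_R)

#' Gradient magnitude and direction of an image
#'
#' Particle edges carry a strong intensity gradient regardless of background
#' level, which is what makes gradient statistics useful for segmenting
#' micrographs with uneven backgrounds. Gradients use the Sobel-normalized
#' centered difference stencil with edge replication at the borders; the
#' magnitude is \code{sqrt(d_row^2 + d_col^2)} and the direction
#' \code{atan2(d_col, d_row)}.
#'
#' @param img a [GrayImage-class].
#' @return A [GradientImage-class].
#' @examples
#' g <- gradientImage(grayImage(matrix(0:15, 16, 16, byrow = TRUE) * 10L))
#' range(g@magnitude[8, ])
#' @export
gradientImage <- function(img) {
  stopifnot(is(img, "GrayImage"))
  px <- pixels(img) + 0.0
  gr <- .convolve2(px, .SOBEL_R)
  gc <- .convolve2(px, .SOBEL_C)
  new("GradientImage", magnitude = sqrt(gr^2 + gc^2),
      direction = atan2(gc, gr))
}

# 2-D correlation with edge replication via EBImage
.convolve2 <- function(m, kernel) {
  out <- EBImage::filter2(EBImage::Image(m), kernel, boundary = "replicate")
  EBImage::imageData(out)
}

#' Max-normalized histogram of gradient magnitudes
#'
#' Uniform bins spanning \code{[0, max magnitude]}; the bin frequencies are
#' normalized by the maximum frequency (\code{P = f / fmax}), the form the
#' slope difference construction operates on.
#'
#' @param grad a [GradientImage-class].
#' @param nBins number of bins (>= 16).
#' @return A [LevelHistogram-class] with \code{domain = "gradient"}.
#' @export
gradientHistogram <- function(grad, nBins = 256L) {
  stopifnot(is(grad, "GradientImage"))
  nBins <- as.integer(nBins)
  if (nBins < 16L) stop("nBins must be >= 16")
  mag <- as.numeric(grad@magnitude)
  mx <- max(mag)
  if (mx <= 0) stop("degenerate gradient histogram: image has no gradient")
  breaks <- seq(0, mx, length.out = nBins + 1L)
  bin <- findInterval(mag, breaks, rightmost.closed = TRUE)
  freq <- tabulate(bin, nbins = nBins)
  .levelHistogram(freq, breaks, "gradient")
}

#' Max-normalized histogram of intensity levels
#'
#' @param img a [GrayImage-class].
#' @param nBins number of bins (>= 16); with \code{nBins = 2^bitdepth} each
#'   bin is one intensity level.
#' @return A [LevelHistogram-class] with \code{domain = "intensity"}.
#' @export
intensityHistogram <- function(img, nBins = 256L) {
  stopifnot(is(img, "GrayImage"))
  nBins <- as.integer(nBins)
  if (nBins < 16L) stop("nBins must be >= 16")
  L <- nLevels(img)
  breaks <- seq(-0.5, L - 0.5, length.out = nBins + 1L)
  bin <- findInterval(as.numeric(pixels(img)), breaks,
                      rightmost.closed = TRUE)
  freq <- tabulate(bin, nbins = nBins)
  .levelHistogram(freq, breaks, "intensity")
}

.levelHistogram <- function(freq, breaks, domain) {
  fmax <- max(freq)
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  new("LevelHistogram", levels = centers, freq = as.integer(freq),
      P = freq / fmax, fmax = as.integer(fmax), breaks = breaks,
      domain = domain)
}

#' Slope difference distribution of a histogram
#'
#' For each interior bin \code{n}, fits a least-squares line to the
#' \code{fitWindow + 1} histogram points on each side (\code{n-W..n} and
#' \code{n..n+W}) and takes the slope difference \code{s(n) = aL(n) - aR(n)}.
#' Positive maxima of \code{s} mark the centers of intensity clusters. The
#' histogram is Gaussian-smoothed before slope fitting (raw counts make the
#' derivative cross zero spuriously); \code{smoothSigma = 0} disables
#' smoothing. The derivative \code{ds/dn} uses central differences; the first
#' and last \code{W} bins have no defined slope and are excluded.
#'
#' @param hist a [LevelHistogram-class].
#' @param fitWindow W, points on each side used for the line fits (>= 2).
#' @param smoothSigma Gaussian smoothing sigma in bins.
#' @return An [SDDProfile-class] (candidates not yet populated).
#' @seealso [findCandidates()], [selectRange()]
#' @export
slopeDifference <- function(hist, fitWindow = 5L, smoothSigma = 2) {
  stopifnot(is(hist, "LevelHistogram"))
  W <- as.integer(fitWindow)
  if (W < 2L) stop("fitWindow must be >= 2")
  nb <- length(hist@P)
  if (nb < 2L * W + 1L) stop("too few histogram bins for the fit window")
  P <- .gaussSmooth(hist@P, smoothSigma)
  # least-squares slope over W+1 equally spaced points = fixed linear weights
  x <- 0:W
  cw <- (x - mean(x)) / sum((x - mean(x))^2)
  s <- rep(NA_real_, nb)
  for (n in (W + 1L):(nb - W)) {
    aL <- sum(cw * P[(n - W):n])
    aR <- sum(cw * P[n:(n + W)])
    s[n] <- aL - aR
  }
  ds <- rep(NA_real_, nb)
  idx <- 2:(nb - 1L)
  ds[idx] <- (s[idx + 1L] - s[idx - 1L]) / 2
  new("SDDProfile", levels = hist@levels, P = P, s = s, ds = ds,
      fitWindow = W, domain = hist@domain)
}

.gaussSmooth <- function(v, sigma) {
  if (sigma <= 0) return(v)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  # replicate-pad so the ends are not pulled toward zero
  vp <- c(rep(v[1L], r), v, rep(v[length(v)], r))
  as.numeric(stats::filter(vp, k, sides = 2))[(r + 1L):(r + length(v))]
}

#' Locate candidate thresholds on an SDD profile
#'
#' Candidates are the levels where \code{ds/dn} crosses zero from positive to
#' negative (local maxima of \code{s}) with \code{s > 0} there -- the centers
#' of the histogram's intensity clusters. The sub-bin crossing position is
#' refined by linear interpolation of \code{ds} between the bracketing
#' samples and then reported as the nearest integer level; when two crossings
#' round to the same level the lower one wins.
#'
#' @param profile an [SDDProfile-class].
#' @return The profile with \code{candidates} populated (ascending).
#' @export
findCandidates <- function(profile) {
  stopifnot(is(profile, "SDDProfile"))
  ds <- profile@ds; s <- profile@s
  nb <- length(ds)
  cand <- numeric(0)
  for (i in seq_len(nb - 1L)) {
    if (is.na(ds[i]) || is.na(ds[i + 1L])) next
    if (ds[i] > 0 && ds[i + 1L] <= 0) {
      x0 <- i + ds[i] / (ds[i] - ds[i + 1L])
      n0 <- as.integer(round(x0))
      if (is.na(s[n0]) || s[n0] <= 0) next
      # map fractional bin position to the level scale
      lev <- stats::approx(seq_len(nb), profile@levels, xout = x0)$y
      cand <- c(cand, round(lev))
    }
  }
  cand <- sort(unique(as.integer(cand)))
  if (!length(cand))
    stop("no cluster centers; image may be structureless")
  initialize(profile, candidates = cand)
}

#' Select the threshold search range [A, B]
#'
#' The upper limit B differentiates the background from particles; the lower
#' limit A differentiates particles with different intensities. In
#' \code{auto} mode the range spans the candidate set; in \code{manual} mode
#' the supplied limits are used and candidates outside them are dropped.
#'
#' @param profile an [SDDProfile-class] with candidates populated.
#' @param mode \code{"auto"} or \code{"manual"}.
#' @param A,B manual range limits (levels); required for manual mode.
#' @return The profile with the range set and candidates filtered.
#' @export
selectRange <- function(profile, mode = c("auto", "manual"),
                        A = NULL, B = NULL) {
  stopifnot(is(profile, "SDDProfile"))
  mode <- match.arg(mode)
  cand <- profile@candidates
  if (!length(cand)) stop("candidates must be populated before range selection")
  if (mode == "auto") {
    A <- min(cand); B <- max(cand)
  } else {
    if (is.null(A) || is.null(B)) stop("manual mode requires A and B")
    if (A > B) stop("range limit A must be <= B")
  }
  keep <- cand[cand >= A & cand <= B]
  if (!length(keep)) stop("no candidates inside the selected range [A, B]")
  initialize(profile, candidates = keep, rangeA = as.numeric(A),
             rangeB = as.numeric(B))
}

#' Write an SDD profile as a diagnostic CSV
#'
#' Columns \code{level, P, s, ds}, one row per bin, for plotting the slope
#' difference and derivative curves alongside the candidate markers.
#'
#' @param profile an [SDDProfile-class].
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeSDDProfile <- function(profile, path) {
  utils::write.csv(
    data.frame(level = profile@levels, P = profile@P, s = profile@s,
               ds = profile@ds),
    path, row.names = FALSE)
  invisible(path)
}
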