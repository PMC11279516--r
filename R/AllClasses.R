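#' @import methods
NULL

#' GrayImage: canonical 2-D grayscale intensity raster
#'
#' The pipeline's universal currency. Pixels are integer intensity levels on
#' \code{0..L-1} with \code{L = 2^bitdepth}; all histogram arithmetic in the
#' package is done on this integer level set so bin identity is unambiguous.
#'
#' @slot pixels integer matrix of intensity levels, indexed \code{[row, col]}.
#' @slot bitdepth integer, 8 or 16.
#' @slot pixelSize numeric, physical length per pixel (nm/px), \code{NA} if
#'   unknown.
#'
#' @seealso [grayImage()], [readGrayImage()]
#' @exportClass GrayImage
setClass("GrayImage",
  representation(pixels = "matrix", bitdepth = "integer",
                 pixelSize = "numeric"),
  prototype(bitdepth = 8L, pixelSize = NA_real_))

setValidity("GrayImage", function(object) {
  px <- object@pixels
  if (!is.numeric(px)) return("pixels must be a numeric matrix")
  if (nrow(px) < 8L || ncol(px) < 8L)
    return("image must be at least 8 x 8 pixels")
  if (!(object@bitdepth %in% c(8L, 16L)))
    return("bitdepth must be 8 or 16")
  L <- 2^object@bitdepth
  if (anyNA(px)) return("pixels must not contain NA")
  if (min(px) < 0 || max(px) > L - 1)
    return(sprintf("pixel values must lie in [0, %d]", L - 1))
  if (any(px != round(px)))
    return("pixel values must be integer levels")
  TRUE
})

#' Construct a GrayImage
#'
#' @param pixels numeric/integer matrix of intensity levels \code{[row, col]}.
#' @param bitdepth 8 or 16.
#' @param pixelSize optional physical pixel size (nm/px).
#' @return A [GrayImage-class] object.
#' @examples
#' img <- grayImage(matrix(128L, 16, 16))
#' bitDepth(img)
#' @export
grayImage <- function(pixels, bitdepth = 8L, pixelSize = NA_real_) {
  storage.mode(pixels) <- "integer"
  new("GrayImage", pixels = pixels, bitdepth = as.integer(bitdepth),
      pixelSize = as.numeric(pixelSize))
}

#' @describeIn grayImage Pixel matrix accessor.
#' @param x,object a \code{GrayImage}.
#' @export
pixels <- function(x) x@pixels

#' @describeIn grayImage Bit depth accessor.
#' @export
bitDepth <- function(x) x@bitdepth

#' @describeIn grayImage Number of intensity levels \code{L = 2^bitdepth}.
#' @export
nLevels <- function(x) as.integer(2^x@bitdepth)

#' @describeIn grayImage Physical pixel size (nm/px) or NA.
#' @export
pixelSize <- function(x) x@pixelSize

#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage: %d x %d, %d-bit, levels [%d, %d]%s\n",
              nrow(object@pixels), ncol(object@pixels), object@bitdepth,
              min(object@pixels), max(object@pixels),
              if (is.na(object@pixelSize)) ""
              else sprintf(", %.3g nm/px", object@pixelSize)))
})

#' GradientImage: gradient magnitude and direction of a GrayImage
#'
#' @slot magnitude numeric matrix, gradient magnitude (levels/pixel), >= 0.
#' @slot direction numeric matrix, gradient direction in (-pi, pi]
#'   (\code{atan2} of the row/column derivatives).
#' @seealso [gradientImage()]
#' @exportClass GradientImage
setClass("GradientImage",
  representation(magnitude = "matrix", direction = "matrix"))

setValidity("GradientImage", function(object) {
  if (!identical(dim(object@magnitude), dim(object@direction)))
    return("magnitude and direction must have equal dimensions")
  if (min(object@magnitude) < 0) return("magnitude must be non-negative")
  TRUE
})

setMethod("show", "GradientImage", function(object) {
  cat(sprintf("GradientImage: %d x %d, |grad| in [%.3g, %.3g]\n",
              nrow(object@magnitude), ncol(object@magnitude),
              min(object@magnitude), max(object@magnitude)))
})

#' LevelHistogram: normalized histogram over intensity or gradient levels
#'
#' Frequencies are max-normalized (\code{P = freq / max(freq)}) as required by
#' the slope difference construction, not sum-normalized.
#'
#' @slot levels numeric vector of bin centers, on the level scale.
#' @slot freq integer vector of counts per bin.
#' @slot P numeric vector, \code{freq / fmax}.
#' @slot fmax maximum frequency.
#' @slot breaks numeric vector of bin edges (length \code{nbins + 1}).
#' @slot domain \code{"intensity"} or \code{"gradient"}.
#' @seealso [gradientHistogram()], [intensityHistogram()]
#' @exportClass LevelHistogram
setClass("LevelHistogram",
  representation(levels = "numeric", freq = "integer", P = "numeric",
                 fmax = "integer", breaks = "numeric", domain = "character"))

setValidity("LevelHistogram", function(object) {
  n <- length(object@levels)
  if (length(object@freq) != n || length(object@P) != n)
    return("levels, freq and P must have equal length")
  if (length(object@breaks) != n + 1L)
    return("breaks must have length(levels) + 1")
  if (object@fmax > 0L && abs(max(object@P) - 1) > 1e-12)
    return("max(P) must equal 1 when any bin is occupied")
  if (!(object@domain %in% c("intensity", "gradient")))
    return("domain must be 'intensity' or 'gradient'")
  TRUE
})

setMethod("show", "LevelHistogram", function(object) {
  cat(sprintf("LevelHistogram (%s domain): %d bins over [%.4g, %.4g], fmax = %d\n",
              object@domain, length(object@levels), min(object@breaks),
              max(object@breaks), object@fmax))
})

#' SDDProfile: slope difference distribution over histogram levels
#'
#' Holds the (optionally smoothed) normalized histogram \code{P}, the slope
#' difference curve \code{s(n) = aL(n) - aR(n)}, its derivative \code{ds/dn},
#' the candidate thresholds (zero crossings of \code{ds} with positive
#' \code{s}, i.e. local maxima of \code{s} -- intensity-cluster centers), and
#' the selected search range \code{[A, B]}.
#'
#' @slot levels bin-center levels (same scale as the source histogram).
#' @slot P smoothed, max-normalized histogram values used for slope fitting.
#' @slot s slope difference curve; \code{NA} at the \code{fitWindow} boundary
#'   bins where slopes are undefined.
#' @slot ds central-difference derivative of \code{s}.
#' @slot candidates integer level values of candidate thresholds, ascending.
#' @slot rangeA,rangeB numeric search-range limits (NA before range selection).
#' @slot fitWindow integer, points on each side used for least-squares slopes.
#' @slot domain \code{"intensity"} or \code{"gradient"}.
#' @seealso [slopeDifference()], [findCandidates()], [selectRange()]
#' @exportClass SDDProfile
setClass("SDDProfile",
  representation(levels = "numeric", P = "numeric", s = "numeric",
                 ds = "numeric", candidates = "integer",
                 rangeA = "numeric", rangeB = "numeric",
                 fitWindow = "integer", domain = "character"),
  prototype(candidates = integer(0), rangeA = NA_real_, rangeB = NA_real_))

setValidity("SDDProfile", function(object) {
  n <- length(object@levels)
  if (length(object@P) != n || length(object@s) != n || length(object@ds) != n)
    return("levels, P, s and ds must have equal length")
  if (object@fitWindow < 2L) return("fitWindow must be >= 2")
  if (!is.na(object@rangeA) && !is.na(object@rangeB)) {
    if (object@rangeA > object@rangeB) return("range A must be <= B")
    cand <- object@candidates
    if (length(cand) &&
        (min(cand) < object@rangeA || max(cand) > object@rangeB))
      return("all candidates must lie within [A, B] once the range is set")
  }
  TRUE
})

#' @describeIn slopeDifference Candidate threshold levels of a profile.
#' @export
candidates <- function(x) x@candidates

#' @describeIn slopeDifference Search range \code{c(A, B)} of a profile.
#' @export
searchRange <- function(x) c(A = x@rangeA, B = x@rangeB)

setMethod("show", "SDDProfile", function(object) {
  cat(sprintf("SDDProfile (%s domain): %d bins, fit window %d\n",
              object@domain, length(object@levels), object@fitWindow))
  if (length(object@candidates))
    cat("  candidates:", paste(object@candidates, collapse = ", "), "\n")
  if (!is.na(object@rangeA))
    cat(sprintf("  range [A, B] = [%g, %g]\n", object@rangeA, object@rangeB))
})

#' ThresholdSearchTrace: record of the entropy-optimized threshold search
#'
#' @slot iterations data.frame with columns \code{iteration}, \code{level},
#'   \code{H} (bits): every entropy evaluation in search order.
#' @slot selected integer, the selected threshold level.
#' @slot Hfinal total Shannon entropy (bits) at the selected threshold.
#' @slot Hparts named numeric, \code{c(foreground=, background=)} entropies.
#' @seealso [binarySearchThreshold()]
#' @exportClass ThresholdSearchTrace
setClass("ThresholdSearchTrace",
  representation(iterations = "data.frame", selected = "integer",
                 Hfinal = "numeric", Hparts = "numeric"))

setValidity("ThresholdSearchTrace", function(object) {
  it <- object@iterations
  if (!all(c("iteration", "level", "H") %in% names(it)))
    return("iterations must have columns iteration, level, H")
  if (nrow(it) && min(it$H) < 0) return("entropies must be >= 0")
  if (object@Hfinal < 0) return("Hfinal must be >= 0")
  TRUE
})

#' @describeIn binarySearchThreshold Selected threshold level of a trace.
#' @export
selectedThreshold <- function(x) x@selected

#' @describeIn binarySearchThreshold Iteration table of a trace.
#' @export
searchTrace <- function(x) x@iterations

setMethod("show", "ThresholdSearchTrace", function(object) {
  cat(sprintf(
    "ThresholdSearchTrace: threshold %d after %d entropy evaluations, H = %.5f bits\n",
    object@selected, nrow(object@iterations), object@Hfinal))
})

#' SegmentationResult: binary mask, labeled components and contours
#'
#' @slot mask integer matrix, 1 = particle, 0 = background.
#' @slot labels integer matrix of component ids (0 = background),
#'   8-connectivity.
#' @slot nComponents number of components.
#' @slot areas integer vector of per-component pixel counts, indexed by label.
#' @slot contours list (possibly empty until [extractContours()] is called) of
#'   per-component matrices with columns \code{x} (column) and \code{y} (row),
#'   0-based.
#' @seealso [labelComponents()], [extractContours()]
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(mask = "matrix", labels = "matrix",
                 nComponents = "integer", areas = "integer",
                 contours = "list"),
  prototype(contours = list()))

setValidity("SegmentationResult", function(object) {
  if (!identical(dim(object@mask), dim(object@labels)))
    return("mask and labels must have equal dimensions")
  if (!all(object@mask %in% c(0L, 1L))) return("mask must be binary")
  if (!identical(object@labels > 0L, object@mask == 1L))
    return("labels must be positive exactly where mask == 1")
  k <- length(unique(object@labels[object@labels > 0L]))
  if (k != object@nComponents)
    return("nComponents must equal the number of distinct positive labels")
  if (length(object@areas) != object@nComponents)
    return("areas must have one entry per component")
  TRUE
})

#' @describeIn labelComponents Binary mask accessor.
#' @export
segMask <- function(x) x@mask

#' @describeIn labelComponents Label matrix accessor.
#' @export
segLabels <- function(x) x@labels

#' @describeIn labelComponents Number of connected components.
#' @export
nComponents <- function(x) x@nComponents

#' @describeIn labelComponents Per-component pixel areas.
#' @export
componentAreas <- function(x) x@areas

#' @describeIn labelComponents Per-component contours (list of x/y matrices).
#' @export
segContours <- function(x) x@contours

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(
    "SegmentationResult: %d x %d mask, %d components, %d foreground px\n",
    nrow(object@mask), ncol(object@mask), object@nComponents,
    sum(object@mask)))
})

#' SyntheticScene: generative ground truth for a simulated micrograph
#'
#' A fully specified synthetic bright-field TEM-like scene: dark circular
#' particles of distinct sizes and intensities on an intentionally uneven
#' background with sharp-transition regions, plus noise. Regenerating from
#' the same scene reproduces the identical image and ground truth.
#'
#' @slot nParticles particle count.
#' @slot particles data.frame with columns \code{row}, \code{col} (centers,
#'   1-based pixel coordinates), \code{radius} (px), \code{intensity} (level).
#' @slot background list: \code{base} level, \code{rampAmplitude} (levels),
#'   \code{rampCoef} polynomial coefficients, \code{regions} list of
#'   sharp-transition region specs.
#' @slot noise list: \code{gaussianSigma} (levels), \code{poisson} flag.
#' @slot distractors list of curvilinear distractor (membrane-like ribbon)
#'   specs; empty for plain particle scenes.
#' @slot clusters list of aggregate-cluster specs; empty for isolated-particle
#'   scenes.
#' @slot overlapPolicy minimum center separation as a multiple of the radius
#'   sum.
#' @slot seed integer RNG seed.
#' @slot size integer c(height, width) in px.
#' @slot bitdepth image bit depth.
#' @seealso [generateScene()], [renderScene()], [presetScene()]
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(nParticles = "integer", particles = "data.frame",
                 background = "list", noise = "list", distractors = "list",
                 clusters = "list", overlapPolicy = "numeric",
                 seed = "integer", size = "integer", bitdepth = "integer"),
  prototype(distractors = list(), clusters = list(), bitdepth = 8L))

setValidity("SyntheticScene", function(object) {
  p <- object@particles
  if (nrow(p) != object@nParticles)
    return("particles table must have nParticles rows")
  if (nrow(p)) {
    if (!all(c("row", "col", "radius", "intensity") %in% names(p)))
      return("particles needs columns row, col, radius, intensity")
    if (min(p$radius) < 1) return("radii must be >= 1 px")
    h <- object@size[1]; w <- object@size[2]
    if (min(p$row) < 1 || max(p$row) > h || min(p$col) < 1 || max(p$col) > w)
      return("all particle centers must lie inside the canvas")
    L <- 2^object@bitdepth
    if (min(p$intensity) < 0 || max(p$intensity) > L - 1)
      return("particle intensities must be valid levels")
  }
  if (length(object@size) != 2L || any(object@size < 8L))
    return("size must be c(height, width), each >= 8")
  TRUE
})

#' @describeIn generateScene Particle table accessor (centers/radii/levels).
#' @export
sceneParticles <- function(x) x@particles

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf(
    "SyntheticScene: %d x %d px, %d particles, seed %d%s%s\n",
    object@size[1], object@size[2], object@nParticles, object@seed,
    if (length(object@distractors))
      sprintf(", %d distractor ribbons", length(object@distractors)) else "",
    if (length(object@clusters))
      sprintf(", %d aggregate clusters", length(object@clusters)) else ""))
})
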