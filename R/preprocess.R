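#' Denoising configuration
#'
#' Parameters of the non-local means (NLM) pre-processing stage. NLM replaces
#' each pixel by a weighted mean of pixels whose surrounding patches look
#' similar, which suppresses the strong shot/detector noise of low-dose TEM
#' while preserving particle edges.
#'
#' @param patchSize odd patch side length in pixels over which patch
#'   similarity is computed.
#' @param searchWindow odd search window side length in pixels.
#' @param strength filtering parameter \code{h} in intensity levels; ignored
#'   when \code{autoStrength} is \code{TRUE}.
#' @param autoStrength if \code{TRUE} (default), set \code{h = 0.8 *
#'   sigma_hat} from the image's estimated noise standard deviation.
#' @return A validated list of class \code{"DenoiseConfig"}.
#' @export
denoiseConfig <- function(patchSize = 7L, searchWindow = 21L,
                          strength = NULL, autoStrength = is.null(strength)) {
  patchSize <- as.integer(patchSize); searchWindow <- as.integer(searchWindow)
  if (patchSize %% 2L == 0L || searchWindow %% 2L == 0L)
    stop("patchSize and searchWindow must be odd")
  if (patchSize >= searchWindow)
    stop("patchSize must be smaller than searchWindow")
  if (!autoStrength && (is.null(strength) || strength <= 0))
    stop("strength must be > 0 when autoStrength is off")
  structure(list(patchSize = patchSize, searchWindow = searchWindow,
                 strength = strength, autoStrength = autoStrength),
            class = "DenoiseConfig")
}

#' Estimate the noise standard deviation of an image
#'
#' Robust pseudo-residual estimator: the horizontal first difference of a
#' smooth image corrupted by i.i.d. noise of standard deviation sigma has
#' standard deviation \code{sigma * sqrt(2)}; the median absolute deviation
#' makes the estimate insensitive to true edges.
#'
#' @param img a [GrayImage-class].
#' @return Estimated sigma in intensity levels.
#' @export
estimateNoiseSigma <- function(img) {
  px <- pixels(img)
  d <- px[, -1L, drop = FALSE] - px[, -ncol(px), drop = FALSE]
  stats::mad(as.numeric(d), center = 0) / sqrt(2)
}

#' Non-local means denoising
#'
#' The first pre-processing stage of the segmentation pipeline. Output has
#' the same shape and bit depth as the input, with values rounded back onto
#' the integer level set and clamped to \code{[0, L-1]}. Deterministic.
#'
#' @param img a [GrayImage-class].
#' @param cfg a [denoiseConfig()] object.
#' @return A denoised [GrayImage-class].
#' @examples
#' img <- grayImage(matrix(100L, 32, 32))
#' identical(pixels(denoiseNLM(img)), pixels(img))  # flat field is unchanged
#' @export
denoiseNLM <- function(img, cfg = denoiseConfig()) {
  stopifnot(is(img, "GrayImage"), inherits(cfg, "DenoiseConfig"))
  if (cfg$patchSize > min(dim(img)))
    stop("patch larger than image")
  sigma <- estimateNoiseSigma(img)
  h <- if (cfg$autoStrength) max(0.8 * sigma, 1e-6) else cfg$strength
  out <- .nlm_cpp(pixels(img) + 0.0, cfg$patchSize, cfg$searchWindow,
                  h, sigma)
  L1 <- nLevels(img) - 1L
  out <- round(out)
  out[out < 0] <- 0; out[out > L1] <- L1
  storage.mode(out) <- "integer"
  grayImage(out, bitdepth = bitDepth(img), pixelSize = pixelSize(img))
}
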