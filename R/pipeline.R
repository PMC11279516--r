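#' Default pipeline configuration
#'
#' Nested list of every tunable parameter, grouped by stage. The
#' \code{segment.profile} presets encode the two imaging regimes:
#' \code{"particles"} (isolated particles; holes inside a particle are
#' artifacts, so they are filled) and \code{"aggregates"} (dense aggregates;
#' pores between particles are real structure, so hole filling is off).
#'
#' @return Nested configuration list.
#' @export
defaultConfig <- function() {
  list(
    denoise = list(enabled = TRUE, patch_size = 7L, search_window = 21L,
                   strength = NULL, auto_strength = TRUE),
    sdd = list(n_bins = 256L, fit_window = 5L, smooth_sigma = 2,
               domain = "intensity", range_mode = "auto",
               range_A = NULL, range_B = NULL),
    # exhaustive argmax over the candidate set is the default: the candidate
    # list is short (tens at most), and the binary-search shortcut can land
    # on a secondary entropy maximum inside the background band when the
    # entropy sequence is not unimodal (set exhaustive = FALSE to use it)
    entropy = list(search_space = "candidates", exhaustive = TRUE,
                   polarity = "dark"),
    segment = list(polarity = "dark", min_area = 9L, max_area = NULL,
                   fill_holes = NULL, convexity_min = NULL,
                   contour_method = "boundary", profile = "particles"),
    baseline = list(method = "histogram", block_size = 51L, offset = 5),
    grid = list(cell_size = 10L, origin = c(0L, 0L), coverage_frac = 0.5,
                scan_alignments = FALSE)
  )
}

#' Read a pipeline configuration file
#'
#' YAML with the same nested sections and keys as [defaultConfig()]
#' (\code{denoise.*}, \code{sdd.*}, \code{entropy.*}, \code{segment.*},
#' \code{baseline.*}, \code{grid.*}). Values override the defaults; unknown
#' sections or keys are rejected so every run's parameters are auditable.
#'
#' @param path YAML file path.
#' @param base configuration to override (default [defaultConfig()]).
#' @return Merged configuration list.
#' @export
readConfig <- function(path, base = defaultConfig()) {
  user <- yaml::read_yaml(path)
  mergeConfig(base, user)
}

#' @describeIn readConfig Merge a partial configuration (nested list) into a
#'   base configuration, rejecting unknown keys.
#' @param override partial nested configuration list.
#' @export
mergeConfig <- function(base, override) {
  for (sec in names(override)) {
    if (!sec %in% names(base)) stop("unknown config section: ", sec)
    for (key in names(override[[sec]])) {
      if (!key %in% names(base[[sec]]))
        stop("unknown config key: ", sec, ".", key)
      base[[sec]][[key]] <- override[[sec]][[key]]
    }
  }
  base
}

# resolve profile-dependent defaults
.resolveSegment <- function(segCfg) {
  if (is.null(segCfg$fill_holes))
    segCfg$fill_holes <- identical(segCfg$profile, "particles")
  segCfg
}

#' Run the full entropy-optimized SDD segmentation pipeline
#'
#' Denoise (optional), build the histogram in the configured domain, compute
#' the slope difference distribution, locate candidate thresholds, select the
#' search range, pick the threshold by the entropy-optimized binary search,
#' binarize, post-process, label components and extract contours.
#'
#' @param img a [GrayImage-class].
#' @param config configuration list (see [defaultConfig()]).
#' @return A list with \code{result} ([SegmentationResult-class]),
#'   \code{threshold} (selected level), \code{trace}
#'   ([ThresholdSearchTrace-class]), \code{profile} ([SDDProfile-class]),
#'   \code{denoised} (the image actually thresholded) and \code{config}
#'   (fully resolved).
#' @examples
#' \donttest{
#' sc <- presetScene("uneven_1028", seed = 1)
#' ren <- renderScene(sc)
#' out <- seosddSegment(ren$img)
#' nComponents(out$result)
#' }
#' @export
seosddSegment <- function(img, config = defaultConfig()) {
  stopifnot(is(img, "GrayImage"))
  config$segment <- .resolveSegment(config$segment)
  den <- if (isTRUE(config$denoise$enabled)) {
    cfg <- denoiseConfig(config$denoise$patch_size,
                         config$denoise$search_window,
                         strength = config$denoise$strength,
                         autoStrength = isTRUE(config$denoise$auto_strength))
    denoiseNLM(img, cfg)
  } else img

  hist <- if (identical(config$sdd$domain, "gradient"))
    gradientHistogram(gradientImage(den), config$sdd$n_bins)
  else
    intensityHistogram(den, config$sdd$n_bins)
  profile <- slopeDifference(hist, config$sdd$fit_window,
                             config$sdd$smooth_sigma)
  profile <- findCandidates(profile)
  profile <- selectRange(profile, config$sdd$range_mode,
                         A = config$sdd$range_A, B = config$sdd$range_B)
  if (identical(config$sdd$domain, "gradient"))
    profile <- .gradientToIntensity(profile, den, config$sdd$n_bins)

  trace <- binarySearchThreshold(
    den, profile, polarity = config$entropy$polarity,
    exhaustive = isTRUE(config$entropy$exhaustive),
    searchSpace = config$entropy$search_space)

  mask <- binarize(den, selectedThreshold(trace), config$segment$polarity)
  mask <- postprocessMask(mask, minArea = config$segment$min_area,
                          fillHoles = isTRUE(config$segment$fill_holes),
                          convexityMin = config$segment$convexity_min,
                          maxArea = config$segment$max_area)
  result <- labelComponents(mask)
  result <- extractContours(result, config$segment$contour_method, img = den)
  list(result = result, threshold = selectedThreshold(trace), trace = trace,
       profile = profile, denoised = den, config = config)
}

# A gradient-domain candidate lives on the gradient-magnitude level scale;
# the binarization threshold must be an intensity level. The mapping keeps
# the candidate's relative histogram position: bin k of the gradient
# histogram maps to the intensity level at the same relative position of the
# intensity range.
.gradientToIntensity <- function(profile, img, nBins) {
  L1 <- nLevels(img) - 1
  span <- max(profile@levels) - min(profile@levels)
  rel <- (profile@candidates - min(profile@levels)) / span
  mapped <- sort(unique(as.integer(round(rel * L1))))
  mapped <- mapped[mapped > 0 & mapped < L1]
  if (!length(mapped)) stop("no usable intensity thresholds after mapping")
  initialize(profile, candidates = mapped,
             rangeA = as.numeric(min(mapped)),
             rangeB = as.numeric(max(mapped)), domain = "intensity")
}

#' Run a baseline segmenter with the same post-processing as the pipeline
#'
#' @param img a [GrayImage-class].
#' @param method \code{"histogram"} (Otsu) or \code{"dynamic"}
#'   (adaptive mean).
#' @param config configuration list.
#' @return A list with \code{result} and, for histogram, \code{threshold}.
#' @export
baselineSegment <- function(img, method = c("histogram", "dynamic"),
                            config = defaultConfig()) {
  method <- match.arg(method)
  config$segment <- .resolveSegment(config$segment)
  den <- if (isTRUE(config$denoise$enabled)) denoiseNLM(img) else img
  t <- NA_integer_
  if (method == "histogram") {
    ht <- histogramThreshold(den, config$segment$polarity)
    mask <- ht$mask; t <- ht$t
  } else {
    mask <- dynamicThreshold(den, config$baseline$block_size,
                             config$baseline$offset,
                             config$segment$polarity)
  }
  mask <- postprocessMask(mask, minArea = config$segment$min_area,
                          fillHoles = isTRUE(config$segment$fill_holes),
                          convexityMin = config$segment$convexity_min,
                          maxArea = config$segment$max_area)
  list(result = labelComponents(mask), threshold = t)
}

#' Three-way method comparison on one image
#'
#' Runs the entropy-optimized SDD pipeline plus both baselines on the same
#' image (sharing the denoised input and post-processing), counts particles,
#' and tabulates accuracy or relative error against the reference.
#'
#' @param img a [GrayImage-class].
#' @param reference reference particle count.
#' @param referenceKind \code{"truth"} or \code{"manual"}.
#' @param mode counting mode, \code{"components"} or \code{"grid"}.
#' @param config configuration list.
#' @return A list with \code{report} (the comparison-table data.frame),
#'   \code{counts}, and \code{results} (per-method
#'   [SegmentationResult-class]).
#' @export
compareMethods <- function(img, reference,
                           referenceKind = c("truth", "manual"),
                           mode = c("components", "grid"),
                           config = defaultConfig()) {
  referenceKind <- match.arg(referenceKind)
  mode <- match.arg(mode)
  config$segment <- .resolveSegment(config$segment)
  den <- if (isTRUE(config$denoise$enabled)) denoiseNLM(img) else img
  cfgNoDen <- config; cfgNoDen$denoise$enabled <- FALSE
  seo <- seosddSegment(den, cfgNoDen)
  hst <- baselineSegment(den, "histogram", cfgNoDen)
  dyn <- baselineSegment(den, "dynamic", cfgNoDen)
  grid <- if (mode == "grid")
    gridSpec(config$grid$cell_size, config$grid$origin,
             config$grid$coverage_frac) else NULL
  counts <- c(
    "SEO-SDD" = countParticles(seo$result, mode, grid),
    "Dynamic threshold" = countParticles(dyn$result, mode, grid),
    "Histogram threshold" = countParticles(hst$result, mode, grid))
  list(report = countReport(counts, reference, referenceKind),
       counts = counts,
       results = list(seosdd = seo$result, dynamic = dyn$result,
                      histogram = hst$result),
       threshold = seo$threshold)
}
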