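#' Generate a synthetic micrograph scene
#'
#' Builds the generative ground truth for a bright-field TEM-like test image:
#' dark circular particles of distinct sizes and intensities placed by dart
#' throwing on an intentionally uneven background (smooth low-order ramp plus
#' sharp-transition regions), with additive noise. The scene records every
#' particle's center, radius and intensity, so the rendered image comes with
#' exact per-particle ground truth.
#'
#' @param nParticles number of particles (>= 0).
#' @param size integer c(height, width) canvas in pixels.
#' @param radiusRange particle radii are drawn uniformly in this range (px).
#' @param intensityRange particle intensities are drawn uniformly in this
#'   dark band (levels).
#' @param background list with \code{base} level, \code{rampAmplitude}
#'   (levels, peak amplitude of the smooth polynomial ramp), and
#'   \code{regions}, a list of sharp-transition region specs (see
#'   [presetScene()] for the ring example).
#' @param noise list with \code{gaussianSigma} (levels) and \code{poisson}
#'   flag.
#' @param overlapPolicy minimum center separation as a multiple of the two
#'   radii's sum; values below 1 permit slight overlap, reproducing the
#'   closely-spaced-particle merging seen in real micrographs.
#' @param clusters optional list of aggregate-cluster specs (each a list with
#'   \code{row}, \code{col}, \code{nMembers}, \code{memberRadius},
#'   \code{ringRadius}, \code{intensity}); members are placed on a ring and
#'   overlap, enclosing an interior pore.
#' @param distractors optional list of curvilinear ribbon specs (each a list
#'   with \code{row}, \code{col}, \code{radius}, \code{width},
#'   \code{spanDeg}, \code{startDeg}, \code{intensity}).
#' @param seed RNG seed; identical seeds give identical scenes.
#' @param maxAttempts dart-throwing attempt budget per particle.
#' @return A [SyntheticScene-class].
#' @export
generateScene <- function(nParticles = 1028L, size = c(1024L, 1024L),
                          radiusRange = c(3, 8), intensityRange = c(40, 120),
                          background = list(base = 180, rampAmplitude = 30,
                                            regions = list()),
                          noise = list(gaussianSigma = 8, poisson = FALSE),
                          overlapPolicy = 0.9, clusters = list(),
                          distractors = list(), seed = 42L,
                          maxAttempts = 200L) {
  nParticles <- as.integer(nParticles)
  size <- as.integer(size)
  if (nParticles < 0L) stop("nParticles must be >= 0")
  set.seed(as.integer(seed))
  h <- size[1]; w <- size[2]

  # ribbon centerline samples, so particles keep their distance from them
  ribbonPts <- do.call(rbind, lapply(distractors, .ribbonCenterline))

  rows <- cols <- rad <- inten <- numeric(0)
  # cluster members first: deterministic ring placement with overlap (and an
  # interior pore), the aggregate geometry of dense nanoparticle suspensions
  for (cl in clusters) {
    th <- seq(0, 2 * pi, length.out = cl$nMembers + 1L)[-(cl$nMembers + 1L)]
    th <- th + stats::runif(1, 0, 2 * pi / cl$nMembers)
    rows <- c(rows, cl$row + cl$ringRadius * sin(th))
    cols <- c(cols, cl$col + cl$ringRadius * cos(th))
    rad <- c(rad, rep(cl$memberRadius, cl$nMembers))
    inten <- c(inten, rep(cl$intensity, cl$nMembers) +
                 stats::runif(cl$nMembers, -10, 10))
  }
  nFree <- nParticles - length(rows)
  if (nFree < 0L) stop("clusters already contain more than nParticles members")
  placed <- 0L
  while (placed < nFree) {
    ok <- FALSE
    for (a in seq_len(maxAttempts)) {
      r <- stats::runif(1, radiusRange[1], radiusRange[2])
      cy <- stats::runif(1, r + 1, h - r)
      cx <- stats::runif(1, r + 1, w - r)
      if (length(rows)) {
        d2 <- (rows - cy)^2 + (cols - cx)^2
        if (any(d2 < (overlapPolicy * (rad + r))^2)) next
      }
      if (!is.null(ribbonPts)) {
        dd <- (ribbonPts[, 1] - cy)^2 + (ribbonPts[, 2] - cx)^2
        if (any(dd < (r + ribbonPts[, 3] + 3)^2)) next
      }
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place all particles within the attempt budget; ",
           "lower the density (fewer particles or a larger canvas)")
    rows <- c(rows, cy); cols <- c(cols, cx)
    rad <- c(rad, r)
    inten <- c(inten, stats::runif(1, intensityRange[1], intensityRange[2]))
    placed <- placed + 1L
  }
  particles <- data.frame(row = rows, col = cols, radius = rad,
                          intensity = pmin(pmax(round(inten), 0), 255))
  new("SyntheticScene", nParticles = nrow(particles), particles = particles,
      background = background, noise = noise, distractors = distractors,
      clusters = clusters, overlapPolicy = overlapPolicy,
      seed = as.integer(seed), size = size, bitdepth = 8L)
}

.ribbonCenterline <- function(rb) {
  th <- seq(rb$startDeg, rb$startDeg + rb$spanDeg, by = 2) * pi / 180
  cbind(rb$row + rb$radius * sin(th), rb$col + rb$radius * cos(th),
        rb$width / 2)
}

#' Render a scene to an image and its ground truth
#'
#' The background is the base level plus a smooth low-order polynomial ramp
#' plus the sharp-transition region shifts; particles are rendered as
#' anti-aliased dark disks at their own intensity (overlaps take the darker
#' value); Gaussian (and optionally Poisson) noise is added last. The truth
#' mask and labels are rendered noise-free from the particle list alone, so
#' background structure never leaks into the truth.
#'
#' @param scene a [SyntheticScene-class].
#' @return A list with \code{img} (a [GrayImage-class]), \code{truth} (a
#'   [SegmentationResult-class] labeling the noise-free particle mask),
#'   \code{distractorMask} (0/1 matrix of rendered ribbon pixels, or
#'   \code{NULL}), and \code{background} (the clean background field).
#' @export
renderScene <- function(scene) {
  stopifnot(is(scene, "SyntheticScene"))
  h <- scene@size[1]; w <- scene@size[2]
  L1 <- 2^scene@bitdepth - 1
  bg <- .renderBackground(scene, h, w)

  img <- bg
  truth <- matrix(0L, h, w)
  p <- scene@particles
  for (i in seq_len(nrow(p))) {
    r <- p$radius[i]; cy <- p$row[i]; cx <- p$col[i]
    r0 <- max(1L, floor(cy - r - 1)); r1 <- min(h, ceiling(cy + r + 1))
    c0 <- max(1L, floor(cx - r - 1)); c1 <- min(w, ceiling(cx + r + 1))
    d <- sqrt(outer((r0:r1 - cy)^2, (c0:c1 - cx)^2, "+"))
    alpha <- pmin(pmax(r + 0.5 - d, 0), 1)
    blend <- img[r0:r1, c0:c1] * (1 - alpha) + p$intensity[i] * alpha
    img[r0:r1, c0:c1] <- pmin(img[r0:r1, c0:c1], blend)
    truth[r0:r1, c0:c1][d <= r] <- 1L
  }

  distractorMask <- NULL
  if (length(scene@distractors)) {
    distractorMask <- matrix(0L, h, w)
    for (rb in scene@distractors) {
      ren <- .renderRibbon(rb, h, w)
      blend <- img * (1 - ren$alpha) + rb$intensity * ren$alpha
      img <- pmin(img, blend)
      distractorMask[ren$alpha >= 0.5] <- 1L
    }
  }

  set.seed(scene@seed + 1L)
  if (isTRUE(scene@noise$poisson)) img <- stats::rpois(length(img), img)
  img <- img + stats::rnorm(h * w, 0, scene@noise$gaussianSigma)
  img <- matrix(pmin(pmax(round(img), 0), L1), h, w)
  storage.mode(img) <- "integer"

  list(img = grayImage(img, bitdepth = scene@bitdepth),
       truth = labelComponents(truth),
       distractorMask = distractorMask,
       background = bg)
}

.renderBackground <- function(scene, h, w) {
  b <- scene@background
  u <- matrix(rep((seq_len(h) - 1) / (h - 1), w), h, w)
  v <- matrix(rep((seq_len(w) - 1) / (w - 1), each = h), h, w)
  # fixed low-order polynomial, scaled to the requested peak amplitude
  f <- 1.0 * (u - 0.5) + 0.7 * (v - 0.5) + 1.6 * (u - 0.5) * (v - 0.5)
  f <- f / max(abs(f))
  bg <- b$base + b$rampAmplitude * f
  for (rg in b$regions) {
    if (identical(rg$shape, "ring")) {
      d <- sqrt(outer((seq_len(h) - rg$row)^2, (seq_len(w) - rg$col)^2, "+"))
      sel <- d >= rg$radius - rg$width / 2 & d <= rg$radius + rg$width / 2
    } else if (identical(rg$shape, "rect")) {
      sel <- matrix(FALSE, h, w)
      sel[rg$rows[1]:rg$rows[2], rg$cols[1]:rg$cols[2]] <- TRUE
    } else stop("unknown sharp-region shape: ", rg$shape)
    bg[sel] <- bg[sel] + rg$shift
  }
  if (!is.null(b$textureAmplitude) && b$textureAmplitude > 0) {
    # blotchy texture: smoothed white noise, emulating e.g. precipitated
    # salt crystals in frozen buffer
    set.seed(scene@seed + 2L)
    tex <- matrix(stats::rnorm(h * w), h, w)
    tex <- EBImage::imageData(EBImage::gblur(EBImage::Image(tex), sigma = 3))
    bg <- bg + b$textureAmplitude * tex / stats::sd(tex)
  }
  bg
}

.renderRibbon <- function(rb, h, w) {
  d <- sqrt(outer((seq_len(h) - rb$row)^2, (seq_len(w) - rb$col)^2, "+"))
  ang <- atan2(outer(seq_len(h) - rb$row, rep(1, w)),
               outer(rep(1, h), seq_len(w) - rb$col)) * 180 / pi
  rel <- (ang - rb$startDeg) %% 360
  inSpan <- rel <= rb$spanDeg
  distArc <- abs(d - rb$radius)
  alpha <- pmin(pmax(rb$width / 2 + 0.5 - distArc, 0), 1)
  alpha[!inSpan] <- 0
  list(alpha = alpha)
}

#' Preset synthetic scenes
#'
#' Three emulations of the validation imagery class the method targets (the
#' real micrographs are not redistributable, so these are declared
#' emulations, not reproductions):
#' \describe{
#'   \item{uneven_1028}{1028 isolated dark particles of distinct sizes and
#'     intensities on an uneven background with a bright ring-shaped
#'     sharp-transition region -- the ground-truth counting benchmark.}
#'   \item{cryo_aggregate}{particles clustered into touching ring-shaped
#'     aggregates with interior pores on a textured, noisy background,
#'     emulating a frozen nanoparticle suspension.}
#'   \item{cell_uptake}{particles plus large high-contrast curvilinear
#'     ribbons emulating stained membrane-like cell structures; the ribbons
#'     have convexity well below 0.5, so the convexity post-filter can
#'     remove them.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @return A [SyntheticScene-class].
#' @export
presetScene <- function(name = c("uneven_1028", "cryo_aggregate",
                                 "cell_uptake"), seed = 42L) {
  name <- match.arg(name)
  switch(name,
    uneven_1028 = generateScene(
      nParticles = 1028L, size = c(1024L, 1024L),
      radiusRange = c(3, 8), intensityRange = c(40, 120),
      background = list(base = 180, rampAmplitude = 30, regions = list(
        list(shape = "ring", row = 560, col = 460, radius = 300,
             width = 70, shift = 40))),
      noise = list(gaussianSigma = 8, poisson = FALSE),
      overlapPolicy = 0.9, seed = seed),
    cryo_aggregate = {
      # dense suspension: aggregates cover a substantial area fraction, as
      # in real cryo micrographs where grid-cell counts reach tens of
      # thousands of particles
      set.seed(seed + 10L)
      nCl <- 56L
      centers <- .dartCenters(nCl, size = 768L, margin = 48L, minSep = 62L)
      clusters <- lapply(seq_len(nCl), function(i)
        list(row = centers[i, 1], col = centers[i, 2], nMembers = 9L,
             memberRadius = 6, ringRadius = 10,
             intensity = stats::runif(1, 50, 105)))
      generateScene(
        nParticles = nCl * 9L + 120L, size = c(768L, 768L),
        radiusRange = c(4, 7), intensityRange = c(45, 110),
        background = list(base = 170, rampAmplitude = 20,
                          textureAmplitude = 8, regions = list(
          list(shape = "ring", row = 384, col = 384, radius = 270,
               width = 40, shift = 30))),
        noise = list(gaussianSigma = 10, poisson = FALSE),
        overlapPolicy = 1.05, clusters = clusters, seed = seed)
    },
    cell_uptake = {
      set.seed(seed + 20L)
      nRb <- 4L
      rc <- .dartCenters(nRb, size = 768L, margin = 150L, minSep = 260L)
      distractors <- lapply(seq_len(nRb), function(i)
        list(row = rc[i, 1], col = rc[i, 2],
             radius = stats::runif(1, 60, 95), width = 5,
             spanDeg = stats::runif(1, 160, 220),
             startDeg = stats::runif(1, 0, 360), intensity = 55))
      generateScene(
        nParticles = 300L, size = c(768L, 768L),
        radiusRange = c(3, 6), intensityRange = c(40, 110),
        background = list(base = 190, rampAmplitude = 25, regions = list()),
        noise = list(gaussianSigma = 6, poisson = FALSE),
        overlapPolicy = 1.0, distractors = distractors, seed = seed)
    })
}

# dart-thrown well-separated centers on a square canvas
.dartCenters <- function(n, size, margin, minSep) {
  pts <- matrix(numeric(0), 0, 2)
  guard <- 0L
  while (nrow(pts) < n) {
    cand <- stats::runif(2, margin, size - margin)
    if (!nrow(pts) || all((pts[, 1] - cand[1])^2 +
                          (pts[, 2] - cand[2])^2 >= minSep^2))
      pts <- rbind(pts, cand)
    guard <- guard + 1L
    if (guard > 10000L) stop("could not place separated centers")
  }
  pts
}

#' Write a scene manifest as JSON-like ground truth
#'
#' The manifest is the ground-truth exchange format: scene parameters and
#' the full particle table. Written as YAML (readable by any YAML parser and
#' by [readSceneManifest()]).
#'
#' @param scene a [SyntheticScene-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeSceneManifest <- function(scene, path) {
  yaml::write_yaml(list(
    nParticles = scene@nParticles, size = as.integer(scene@size),
    seed = scene@seed, bitdepth = scene@bitdepth,
    overlapPolicy = scene@overlapPolicy,
    noise = scene@noise, background = scene@background,
    particles = lapply(seq_len(nrow(scene@particles)), function(i)
      as.list(scene@particles[i, ]))), path)
  invisible(path)
}

#' @describeIn writeSceneManifest Read back a scene manifest; returns a list
#'   with \code{nParticles} and the particle table.
#' @param path manifest path.
#' @export
readSceneManifest <- function(path) {
  m <- yaml::read_yaml(path)
  m$particles <- do.call(rbind, lapply(m$particles, as.data.frame))
  m
}
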