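# Programmatic fixtures shared across test files.

# image with the given integer matrix, recycled to at least 8x8
fixImage <- function(m, bitdepth = 8L) {
  storage.mode(m) <- "integer"
  grayImage(m, bitdepth = bitdepth)
}

# constant image
constImage <- function(value, n = 16L, bitdepth = 8L) {
  fixImage(matrix(as.integer(value), n, n), bitdepth = bitdepth)
}

# image whose levels are drawn i.i.d. from the given level set
levelsImage <- function(levels, counts, n = NULL) {
  v <- rep(as.integer(levels), counts)
  if (is.null(n)) n <- ceiling(sqrt(length(v)))
  if (length(v) < n * n) v <- c(v, rep(levels[1], n * n - length(v)))
  fixImage(matrix(v[seq_len(n * n)], n, n))
}

# rasterized disk mask centered in an n x n canvas
diskMask <- function(r, n = 2L * r + 11L) {
  c0 <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+"))
  m <- matrix(as.integer(d <= r), n, n)
  m
}

# thin open arc (1 px wide S-like curve) in an n x n canvas
arcMask <- function(R = 20L, n = 64L) {
  m <- matrix(0L, n, n)
  th <- seq(0, pi * 1.5, length.out = 400)
  r <- pmin(pmax(round(n / 2 + R * sin(th)), 1), n)
  c <- pmin(pmax(round(n / 2 + R * cos(th)), 1), n)
  m[cbind(r, c)] <- 1L
  m
}

# memoized heavyweight scenes so several test files can share one render +
# segmentation of the same preset
.sceneCache <- new.env(parent = emptyenv())

cachedPipeline <- function(key, compute) {
  if (is.null(.sceneCache[[key]])) .sceneCache[[key]] <- compute()
  .sceneCache[[key]]
}

unevenComparison <- function() {
  cachedPipeline("uneven", function() {
    ren <- renderScene(presetScene("uneven_1028", seed = 42))
    list(render = ren, cmp = compareMethods(ren$img, 1028, "truth"))
  })
}

cryoSegmentation <- function() {
  cachedPipeline("cryo", function() {
    ren <- renderScene(presetScene("cryo_aggregate", seed = 42))
    cfg <- defaultConfig()
    cfg$segment$profile <- "aggregates"
    den <- denoiseNLM(ren$img)
    cfg$denoise$enabled <- FALSE
    seo <- seosddSegment(den, cfg)
    cfgFill <- cfg
    cfgFill$segment$fill_holes <- TRUE
    hist <- baselineSegment(den, "histogram", cfgFill)
    list(render = ren, seo = seo, hist = hist)
  })
}

cellSegmentation <- function() {
  cachedPipeline("cell", function() {
    ren <- renderScene(presetScene("cell_uptake", seed = 42))
    seo <- seosddSegment(ren$img)
    list(render = ren, seo = seo)
  })
}
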