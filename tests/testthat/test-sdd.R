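# helper: build an SDDProfile directly from synthetic s and ds curves so the
# candidate detector can be tested in isolation
profileFrom <- function(s, ds, levels = seq_along(s) - 1) {
  new("SDDProfile", levels = as.numeric(levels), P = rep(0.5, length(s)),
      s = s, ds = ds, fitWindow = 2L, domain = "intensity")
}

test_that("a flat field has zero gradient and a constant offset none", {
  g <- gradientImage(constImage(77))
  expect_true(all(g@magnitude == 0))
  # gradient magnitude is invariant under adding a constant
  px <- matrix(as.integer((1:16 %o% 1:16) %% 120), 16, 16)
  g1 <- gradientImage(fixImage(px))
  g2 <- gradientImage(fixImage(px + 50L))
  expect_equal(g1@magnitude, g2@magnitude)
})

test_that("a vertical step has magnitude proportional to its height", {
  step <- function(h) {
    px <- matrix(100L, 16, 16); px[, 9:16] <- 100L + as.integer(h)
    fixImage(px)
  }
  g1 <- gradientImage(step(40)); g2 <- gradientImage(step(80))
  # maxima sit on the step columns and scale linearly with the height
  expect_equal(max(g2@magnitude), 2 * max(g1@magnitude))
  peakCols <- which(g1@magnitude == max(g1@magnitude), arr.ind = TRUE)[, 2]
  expect_true(all(peakCols %in% c(8L, 9L)))
})

test_that("intensity scaling scales gradient magnitudes linearly", {
  px <- matrix(as.integer((row(matrix(0, 16, 16)) * 5) %% 100), 16, 16)
  g1 <- gradientImage(fixImage(px))
  g2 <- gradientImage(fixImage(px * 2L))
  expect_equal(g2@magnitude, 2 * g1@magnitude)
})

test_that("transposing the image transposes the gradient field", {
  set.seed(3)
  px <- matrix(as.integer(sample(0:255, 256, TRUE)), 16, 16)
  g <- gradientImage(fixImage(px))
  gt <- gradientImage(fixImage(t(px)))
  expect_equal(gt@magnitude, t(g@magnitude))
})

# gradientHistogram requires >= 16 bins for real use; the 10-bin worked
# example exercises the same binning arithmetic directly
.levelHistogramForTest <- function(mag, nBins) {
  breaks <- seq(0, max(mag), length.out = nBins + 1)
  bin <- findInterval(as.numeric(mag), breaks, rightmost.closed = TRUE)
  seosdd:::.levelHistogram(tabulate(bin, nbins = nBins), breaks, "gradient")
}

test_that("gradient histogram normalizes by the maximum frequency", {
  # 100 px of magnitude 1 and 50 of magnitude 9 into 10 bins
  mag <- matrix(c(rep(1, 100), rep(9, 50)), 10, 15)
  g <- new("GradientImage", magnitude = mag, direction = mag * 0)
  h <- gradientHistogram(g, nBins = 16L)
  expect_error(gradientHistogram(g, nBins = 10L), "nBins")
  h10 <- .levelHistogramForTest(mag, 10L)
  expect_equal(sum(h10@freq), 150L)
  expect_equal(h10@freq[2], 100L)   # bin (0.9, 1.8] holds magnitude 1
  expect_equal(h10@freq[10], 50L)   # last bin holds magnitude 9
  expect_equal(h10@P[2], 1.0)
  expect_equal(h10@P[10], 0.5)
  expect_equal(max(h10@P), 1.0)
  # degenerate gradient
  z <- new("GradientImage", magnitude = mag * 0, direction = mag * 0)
  expect_error(gradientHistogram(z), "degenerate")
})

test_that("intensity histogram puts each 8-bit level in its own bin", {
  img <- levelsImage(c(10L, 200L), c(100L, 156L))
  h <- intensityHistogram(img)
  expect_equal(sum(h@freq), 256L)
  expect_equal(h@freq[11], 100L)
  expect_equal(h@freq[201], 156L)
  expect_equal(h@P[201], 1.0)
  expect_equal(h@levels[11], 10)
})

test_that("slope difference vanishes on a linear histogram", {
  h <- seosdd:::.levelHistogram(as.integer(10 + 2 * (0:63)),
                                seq(-0.5, 63.5, length.out = 65), "intensity")
  pr <- slopeDifference(h, fitWindow = 4L, smoothSigma = 0)
  s <- pr@s[!is.na(pr@s)]
  expect_true(all(abs(s) < 1e-10))
})

test_that("slope difference peaks at a triangular apex and dips at a valley", {
  tri <- c(seq(0, 1, length.out = 17), seq(1, 0, length.out = 17)[-1])
  h <- seosdd:::.levelHistogram(as.integer(round(tri * 1600)),
                                seq(-0.5, 32.5, 1), "intensity")
  pr <- slopeDifference(h, fitWindow = 3L, smoothSigma = 0)
  expect_equal(which.max(pr@s), 17L)      # apex bin
  expect_gt(pr@s[17], 0)
  valley <- 1 - tri
  hv <- seosdd:::.levelHistogram(as.integer(round(valley * 1600)),
                                 seq(-0.5, 32.5, 1), "intensity")
  prv <- slopeDifference(hv, fitWindow = 3L, smoothSigma = 0)
  expect_lt(prv@s[17], 0)
  # boundary bins are excluded from the fit
  expect_true(all(is.na(pr@s[1:3])) && all(is.na(pr@s[31:33])))
  expect_error(slopeDifference(h, fitWindow = 20L), "too few")
})

test_that("candidate detection finds each positive maximum of s", {
  # single triangular peak at bin 11 (level 10)
  s1 <- c(rep(NA, 2), seq(-0.2, 0.5, length.out = 9),
          seq(0.5, -0.3, length.out = 10)[-1], rep(NA, 2))
  ds1 <- rep(NA_real_, length(s1))
  idx <- 2:(length(s1) - 1)
  ds1[idx] <- (s1[idx + 1] - s1[idx - 1]) / 2
  pr <- findCandidates(profileFrom(s1, ds1))
  expect_equal(candidates(pr), 10L)

  # two separated positive peaks -> two candidates, sorted
  x <- 0:63
  s2 <- exp(-(x - 15)^2 / 8) + 0.6 * exp(-(x - 45)^2 / 8) - 0.05
  ds2 <- rep(NA_real_, 64)
  ds2[2:63] <- (s2[3:64] - s2[1:62]) / 2
  pr2 <- findCandidates(profileFrom(s2, ds2))
  expect_equal(candidates(pr2), c(15L, 45L))

  # everywhere non-positive s -> error
  s3 <- -exp(-(x - 30)^2 / 50)
  ds3 <- rep(NA_real_, 64)
  ds3[2:63] <- (s3[3:64] - s3[1:62]) / 2
  expect_error(findCandidates(profileFrom(s3, ds3)), "no cluster centers")
})

test_that("candidate detection agrees with brute-force sign enumeration", {
  set.seed(19)
  for (rep in 1:25) {
    x <- 0:127
    k <- sample(2:4, 1)
    s <- rowSums(sapply(seq_len(k), function(i)
      runif(1, 0.3, 1) * exp(-(x - runif(1, 10, 117))^2 /
                               runif(1, 5, 40)))) - 0.02
    ds <- rep(NA_real_, 128)
    ds[2:127] <- (s[3:128] - s[1:126]) / 2
    pr <- try(findCandidates(profileFrom(s, ds)), silent = TRUE)
    # oracle: enumerate all + -> <=0 transitions of ds with positive s
    brute <- integer(0)
    for (i in 2:126) {
      if (!is.na(ds[i]) && !is.na(ds[i + 1]) && ds[i] > 0 && ds[i + 1] <= 0) {
        x0 <- i + ds[i] / (ds[i] - ds[i + 1])
        if (s[round(x0)] > 0) brute <- c(brute, as.integer(round(x0 - 1)))
      }
    }
    brute <- sort(unique(brute))
    if (inherits(pr, "try-error")) {
      expect_length(brute, 0)
    } else {
      expect_equal(candidates(pr), brute)
    }
  }
})

test_that("well-separated histogram modes each yield a nearby candidate", {
  set.seed(23)
  v <- c(round(rnorm(4000, 60, 8)), round(rnorm(4000, 180, 8)))
  v <- as.integer(pmin(pmax(v, 0), 255))
  img <- fixImage(matrix(v[1:(89 * 89)], 89, 89))
  pr <- findCandidates(slopeDifference(intensityHistogram(img)))
  expect_true(any(abs(candidates(pr) - 60) <= 2))
  expect_true(any(abs(candidates(pr) - 180) <= 2))
})

test_that("range selection filters candidates and validates limits", {
  pr <- profileFrom(rep(0.1, 128), rep(NA_real_, 128))
  pr@candidates <- c(10L, 40L, 90L)
  expect_equal(candidates(selectRange(pr, "manual", A = 20, B = 95)),
               c(40L, 90L))
  auto <- selectRange(pr, "auto")
  expect_equal(unname(searchRange(auto)), c(10, 90))
  expect_equal(candidates(auto), c(10L, 40L, 90L))
  expect_error(selectRange(pr, "manual", A = 95, B = 20), "A must be <= B")
  pr@candidates <- 10L
  expect_error(selectRange(pr, "manual", A = 20, B = 30), "no candidates")
})

test_that("the profile CSV diagnostic has the documented columns", {
  d <- withr::local_tempdir()
  img <- levelsImage(c(40L, 200L), c(120L, 136L))
  pr <- slopeDifference(intensityHistogram(img))
  p <- file.path(d, "profile.csv")
  writeSDDProfile(pr, p)
  df <- utils::read.csv(p)
  expect_named(df, c("level", "P", "s", "ds"))
  expect_equal(nrow(df), 256L)
})
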