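test_that("binarize respects polarity and the inversion identity", {
  img <- levelsImage(c(10L, 200L), c(128L, 128L))
  m <- binarize(img, 100, "dark")
  expect_identical(m == 1L, pixels(img) == 10L)
  # all pixels above t, dark polarity -> empty mask
  expect_true(all(binarize(img, 5, "dark") == 0L))
  # binarize(img, t, dark) == binarize(inverted, L-1-t, bright)
  inv <- fixImage(255L - pixels(img))
  expect_identical(binarize(img, 100, "dark"),
                   binarize(inv, 255L - 100L, "bright"))
})

test_that("small, large and non-convex components are filtered", {
  m <- matrix(0L, 40, 40)
  m[5:6, 5:6] <- 1L                 # 4 px: below minArea 5
  m[20:29, 20:29] <- 1L             # 100 px square
  expect_equal(sum(postprocessMask(m, minArea = 5)), 100L)
  expect_equal(sum(postprocessMask(m, minArea = 5, maxArea = 50)), 0L)
  # single 3-px component entirely removed at minArea 5
  m2 <- matrix(0L, 12, 12); m2[4, 4:6] <- 1L
  expect_true(all(postprocessMask(m2, minArea = 5) == 0L))

  # a solid disk is nearly convex and survives the convexity filter
  disk <- diskMask(8)
  expect_equal(postprocessMask(disk, minArea = 0, convexityMin = 0.8), disk)
  # a thin curved arc has a hull far larger than itself and is removed
  arc <- arcMask()
  expect_true(all(postprocessMask(arc, minArea = 0,
                                  convexityMin = 0.8) == 0L))
})

test_that("hole filling closes enclosed pores only when requested", {
  ring <- diskMask(9) - diskMask(4, n = 29)
  storage.mode(ring) <- "integer"
  kept <- postprocessMask(ring, minArea = 0, fillHoles = FALSE)
  expect_identical(kept, ring)
  filled <- postprocessMask(ring, minArea = 0, fillHoles = TRUE)
  expect_identical(filled, diskMask(9))
})

test_that("post-processing is idempotent and monotone in minArea", {
  set.seed(31)
  m <- matrix(as.integer(runif(64^2) < 0.35), 64, 64)
  once <- postprocessMask(m, minArea = 6, fillHoles = TRUE,
                          convexityMin = 0.3)
  twice <- postprocessMask(once, minArea = 6, fillHoles = TRUE,
                           convexityMin = 0.3)
  expect_identical(once, twice)
  counts <- vapply(c(1, 4, 9, 16, 25), function(a)
    nComponents(labelComponents(postprocessMask(m, minArea = a))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(postprocessMask(m, minArea = -1), ">= 0")
})

test_that("labeling uses 8-connectivity and counts components correctly", {
  m <- matrix(0L, 20, 20)
  m[2:5, 2:5] <- 1L; m[10:13, 10:13] <- 1L
  expect_equal(nComponents(labelComponents(m)), 2L)
  expect_equal(sort(componentAreas(labelComponents(m))), c(16L, 16L))
  expect_equal(nComponents(labelComponents(matrix(0L, 10, 10))), 0L)
  # diagonal corner touch joins under 8-connectivity
  d <- matrix(0L, 10, 10)
  d[2:3, 2:3] <- 1L; d[4:5, 4:5] <- 1L
  expect_equal(nComponents(labelComponents(d)), 1L)
  # cross-check against the 4-connectivity labeler on a diagonal-free mask
  m4 <- matrix(0L, 30, 30); m4[3:7, 3:7] <- 1L; m4[15:20, 10:22] <- 1L
  expect_equal(nComponents(labelComponents(m4)),
               max(EBImage::bwlabel(EBImage::Image(m4))))
})

test_that("labels cover exactly the mask and areas sum to the foreground", {
  set.seed(37)
  m <- matrix(as.integer(runif(50^2) < 0.3), 50, 50)
  res <- labelComponents(m)
  expect_identical(segLabels(res) > 0L, segMask(res) == 1L)
  expect_equal(sum(componentAreas(res)), sum(m))
})

test_that("boundary contours have the expected geometry", {
  # 10 x 10 solid square: 36 boundary pixels
  m <- matrix(0L, 20, 20); m[6:15, 4:13] <- 1L
  res <- extractContours(labelComponents(m))
  expect_equal(nrow(segContours(res)[[1]]), 36L)
  # single pixel component contours to itself (0-based x = col, y = row)
  p <- matrix(0L, 10, 10); p[4, 7] <- 1L
  cp <- segContours(extractContours(labelComponents(p)))[[1]]
  expect_equal(unname(cp[1, ]), c(6, 3))
  # every contour pixel touches the background
  res2 <- extractContours(labelComponents(diskMask(7)))
  ct <- segContours(res2)[[1]]
  msk <- diskMask(7)
  pad <- matrix(0L, nrow(msk) + 2, ncol(msk) + 2)
  pad[2:(nrow(msk) + 1), 2:(ncol(msk) + 1)] <- msk
  touches <- apply(ct, 1, function(q) {
    r <- q[2] + 2; c <- q[1] + 2   # padded 1-based
    any(pad[(r - 1):(r + 1), (c - 1):(c + 1)] == 0L)
  })
  expect_true(all(touches))
})

test_that("disk contour perimeter approximates the circle circumference", {
  for (r in c(10, 16, 24)) {
    ct <- segContours(extractContours(labelComponents(diskMask(r))))[[1]]
    d <- sqrt(rowSums((ct - rbind(ct[-1, ], ct[1, , drop = FALSE]))^2))
    expect_lt(abs(sum(d) - 2 * pi * r) / (2 * pi * r), 0.15)
  }
})

test_that("contours are oriented counter-clockwise in the image frame", {
  ct <- segContours(extractContours(labelComponents(diskMask(9))))[[1]]
  x <- ct[, 1]; y <- ct[, 2]
  nx <- c(x[-1], x[1]); ny <- c(y[-1], y[1])
  expect_gte(sum(x * ny - nx * y), 0)
})

test_that("canny contours land on particle boundaries", {
  px <- matrix(200L, 48, 48)
  d <- sqrt(outer((1:48 - 24)^2, (1:48 - 24)^2, "+"))
  px[d <= 10] <- 60L
  img <- fixImage(px)
  res <- labelComponents(binarize(img, 130, "dark"))
  ctB <- segContours(extractContours(res, "boundary"))[[1]]
  ctC <- segContours(extractContours(res, "canny", img = img))[[1]]
  expect_gt(nrow(ctC), 20)
  # every canny edge pixel is within 2 px of the traced boundary
  dd <- vapply(seq_len(nrow(ctC)), function(i)
    min(sqrt((ctB[, 1] - ctC[i, 1])^2 + (ctB[, 2] - ctC[i, 2])^2)),
    numeric(1))
  expect_lt(max(dd), 2.5)
})

test_that("canny on a clean step finds a single thin edge line", {
  px <- matrix(50L, 32, 32); px[, 17:32] <- 200L
  e <- cannyEdges(fixImage(px))
  cols <- unique(which(e == 1L, arr.ind = TRUE)[, 2])
  expect_true(all(cols %in% 15:18))
  expect_true(all(e[, c(1:12, 22:32)] == 0L))
})
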