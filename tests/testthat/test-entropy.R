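test_that("partition entropy matches closed forms for uniform partitions", {
  # two values, split between them: each class single-valued, zero entropy
  two <- levelsImage(c(30L, 220L), c(100L, 156L))
  H <- partitionEntropy(two, 100)
  expect_equal(unname(H), c(0, 0, 0))

  # four equally frequent values split 2|2: 1 bit per class, 2 bits total
  four <- levelsImage(c(10L, 20L, 200L, 210L), c(64L, 64L, 64L, 64L))
  H4 <- partitionEntropy(four, 100)
  expect_equal(unname(H4["foreground"]), 1)
  expect_equal(unname(H4["background"]), 1)
  expect_equal(unname(H4["total"]), 2)

  # uniform over 4 values split 1|3: 0 + log2(3) bits
  H13 <- partitionEntropy(four, 15)
  expect_equal(unname(H13["total"]), log2(3))
  expect_equal(unname(H13["foreground"]), 0)

  # uniform over 3 values entirely on one side with one on the other
  three <- levelsImage(c(10L, 100L, 150L, 200L), c(64L, 64L, 64L, 64L))
  expect_equal(unname(partitionEntropy(three, 50)["total"]), log2(3))
})

test_that("degenerate partitions are rejected", {
  img <- levelsImage(c(100L, 150L), c(128L, 128L))
  expect_error(partitionEntropy(img, 50), "degenerate")
  expect_error(partitionEntropy(img, 300), "threshold")
  # polarity only relabels the parts, never the total
  Hd <- partitionEntropy(img, 120, "dark")
  Hb <- partitionEntropy(img, 120, "bright")
  expect_equal(Hd[["total"]], Hb[["total"]])
  expect_equal(Hd[["foreground"]], Hb[["background"]])
})

test_that("entropy is bounded by the partition sizes", {
  set.seed(5)
  img <- fixImage(matrix(as.integer(sample(0:255, 64^2, TRUE)), 64, 64))
  H <- partitionEntropy(img, 127)
  expect_lte(H[["total"]], 2 * log2(256))
  expect_gte(H[["total"]], 0)
})

test_that("single-candidate search returns immediately with one trace entry", {
  img <- levelsImage(c(40L, 200L), c(100L, 156L))
  pr <- new("SDDProfile", levels = 0:255, P = rep(0.5, 256),
            s = rep(NA_real_, 256), ds = rep(NA_real_, 256),
            candidates = 120L, fitWindow = 2L, domain = "intensity")
  tr <- binarySearchThreshold(img, pr)
  expect_equal(selectedThreshold(tr), 120L)
  expect_equal(nrow(searchTrace(tr)), 1L)
  expect_equal(tr@Hfinal, unname(partitionEntropy(img, 120)["total"]))
})

test_that("binary search equals exhaustive argmax on unimodal entropy", {
  # drive the index search with synthetic entropy sequences: any strictly
  # unimodal H over the candidate list must give the global argmax
  set.seed(101)
  for (rep in 1:100) {
    K <- sample(2:20, 1)
    peak <- sample(seq_len(K), 1)
    H <- c(sort(runif(peak - 1)), 1 + runif(1),
           sort(runif(K - peak), decreasing = TRUE))
    cand <- sort(sample(1:254, K))
    Hof <- function(t) H[match(t, cand)]
    got <- seosdd:::.binarySearchIndex(cand, Hof)
    expect_equal(got$selected, cand[which.max(H)])
    # iteration count bound: each loop evaluates two entropies
    expect_lte(nrow(got$trace), 2 * (ceiling(log2(K)) + 1))
  }
})

test_that("monotone entropy sequences drive the search to an endpoint", {
  cand <- c(10L, 50L, 90L, 130L)
  up <- function(t) match(t, cand) / 4
  down <- function(t) 1 - match(t, cand) / 5
  expect_equal(seosdd:::.binarySearchIndex(cand, up)$selected, 130L)
  expect_equal(seosdd:::.binarySearchIndex(cand, down)$selected, 10L)
})

test_that("bisection can stall on a secondary maximum where exhaustive cannot", {
  # documented divergence: a bimodal entropy sequence over 8 candidates
  cand <- as.integer(seq(10, 150, by = 20))
  H <- c(0.2, 0.9, 0.4, 0.3, 0.35, 0.4, 0.5, 0.45)
  Hof <- function(t) H[match(t, cand)]
  bis <- seosdd:::.binarySearchIndex(cand, Hof)$selected
  exh <- seosdd:::.exhaustiveSearch(cand, Hof)$selected
  expect_equal(exh, cand[2])       # global maximum
  expect_equal(bis, cand[7])       # local maximum in the right half
})

test_that("pipeline search is self-consistent and respects known two-mode data", {
  set.seed(9)
  v <- c(round(rnorm(3000, 60, 6)), round(rnorm(5000, 180, 10)))
  v <- as.integer(pmin(pmax(v, 0), 255))
  img <- fixImage(matrix(v[1:(89 * 89)], 89, 89))
  pr <- selectRange(findCandidates(slopeDifference(intensityHistogram(img))),
                    "auto")
  tr <- binarySearchThreshold(img, pr)
  expect_true(selectedThreshold(tr) %in% candidates(pr))
  expect_equal(tr@Hfinal,
               unname(partitionEntropy(img, selectedThreshold(tr))["total"]))
  expect_equal(sum(tr@Hparts), tr@Hfinal)
})

test_that("threshold choice is invariant under polarity flip plus inversion", {
  # two Gaussian modes with an unambiguous entropy argmax; inverting the
  # image mirrors the histogram, so the selected threshold must mirror too
  # (up to the one level of slack the <= t vs > t convention introduces,
  # plus sub-bin rounding of the mirrored candidates)
  set.seed(13)
  v <- c(round(rnorm(2700, 60, 8)), round(rnorm(5400, 180, 10)))
  v <- as.integer(pmin(pmax(v, 0), 255))
  img <- fixImage(matrix(v[1:(90 * 90)], 90, 90))
  pr <- selectRange(findCandidates(
    slopeDifference(intensityHistogram(img))), "auto")
  tr <- binarySearchThreshold(img, pr, polarity = "dark", exhaustive = TRUE)
  inv <- fixImage(255L - pixels(img))
  prI <- selectRange(findCandidates(
    slopeDifference(intensityHistogram(inv))), "auto")
  trI <- binarySearchThreshold(inv, prI, polarity = "bright",
                               exhaustive = TRUE)
  expect_lte(abs((255L - selectedThreshold(trI)) - selectedThreshold(tr)), 2L)
})

test_that("the search trace CSV includes the normalized entropy column", {
  d <- withr::local_tempdir()
  img <- levelsImage(c(40L, 55L, 200L, 215L), c(64L, 64L, 64L, 64L))
  pr <- new("SDDProfile", levels = 0:255, P = rep(0.5, 256),
            s = rep(NA_real_, 256), ds = rep(NA_real_, 256),
            candidates = c(60L, 120L, 180L), fitWindow = 2L,
            domain = "intensity")
  tr <- binarySearchThreshold(img, pr)
  p <- file.path(d, "trace.csv")
  writeSearchTrace(tr, p)
  df <- utils::read.csv(p)
  expect_named(df, c("iteration", "level", "H", "H_normalized"))
  expect_equal(max(df$H_normalized), 1)
})
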