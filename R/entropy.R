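#' Shannon entropy of a thresholded intensity partition
#'
#' A threshold \code{t} splits the intensity histogram into a low side
#' (levels \code{<= t}) and a high side (levels \code{> t}). Each side's
#' intensity distribution is renormalized within its class and its Shannon
#' entropy computed in bits (\code{0 * log2(0) = 0}); the total is the sum of
#' the two class entropies. Renormalizing per class is what makes the total
#' vary with \code{t} and so drives the threshold search. With the default
#' dark-particle polarity the low side is the particle (foreground) class.
#'
#' @param img a [GrayImage-class].
#' @param t threshold level, \code{0 <= t < L-1}.
#' @param polarity \code{"dark"} (particles darker than background, the
#'   bright-field TEM default) or \code{"bright"}.
#' @return Named numeric \code{c(total=, foreground=, background=)} in bits.
#' @examples
#' px <- matrix(rep(c(10L, 20L, 200L, 210L), each = 64), 16, 16)
#' partitionEntropy(grayImage(px), 100)  # 1 bit per class, 2 bits total
#' @export
partitionEntropy <- function(img, t, polarity = c("dark", "bright")) {
  stopifnot(is(img, "GrayImage"))
  polarity <- match.arg(polarity)
  L <- nLevels(img)
  if (t < 0 || t >= L - 1) stop("threshold must satisfy 0 <= t < L-1")
  counts <- tabulate(as.numeric(pixels(img)) + 1, nbins = L)
  Hs <- .partitionEntropyCounts(counts, t)
  if (is.null(Hs)) stop("degenerate threshold: empty partition")
  if (polarity == "dark")
    c(total = Hs[["low"]] + Hs[["high"]], foreground = Hs[["low"]],
      background = Hs[["high"]])
  else
    c(total = Hs[["low"]] + Hs[["high"]], foreground = Hs[["high"]],
      background = Hs[["low"]])
}

# entropies of the two classes split at t (levels are 0-based); NULL if a
# class is empty
.partitionEntropyCounts <- function(counts, t) {
  lo <- counts[seq_len(t + 1L)]
  hi <- counts[(t + 2L):length(counts)]
  nlo <- sum(lo); nhi <- sum(hi)
  if (nlo == 0L || nhi == 0L) return(NULL)
  c(low = .shannon(lo / nlo), high = .shannon(hi / nhi))
}

.shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy-optimized threshold selection by binary search
#'
#' Selects the binarization threshold from the profile's candidate set (the
#' intensity-cluster centers inside the search range \code{[A, B]}) by a
#' binary search on the sorted candidates: at each step the total partition
#' entropies of the middle candidate and its successor are compared; if
#' \code{H(mid) > H(mid+1)} the search keeps \code{[lo, mid]}, otherwise
#' \code{[mid+1, hi]}, terminating when the range collapses. When the entropy
#' sequence over candidates is unimodal this finds the global entropy
#' maximum in \code{O(log K)} evaluations; on non-unimodal sequences it finds
#' a local maximum (set \code{exhaustive = TRUE} for a full scan). Ties move
#' the search right. Candidates whose threshold would empty a partition score
#' zero entropy.
#'
#' @param img a [GrayImage-class] (typically denoised).
#' @param profile an [SDDProfile-class] with candidates and range set.
#' @param polarity foreground polarity, \code{"dark"} or \code{"bright"}.
#' @param exhaustive if \code{TRUE}, evaluate every candidate and take the
#'   argmax (first maximum on ties) instead of the binary search.
#' @param searchSpace \code{"candidates"} (default: search the candidate
#'   list) or \code{"levels"} (search every integer level in \code{[A, B]},
#'   for sensitivity analysis).
#' @return A [ThresholdSearchTrace-class].
#' @export
binarySearchThreshold <- function(img, profile,
                                  polarity = c("dark", "bright"),
                                  exhaustive = FALSE,
                                  searchSpace = c("candidates", "levels")) {
  stopifnot(is(img, "GrayImage"), is(profile, "SDDProfile"))
  polarity <- match.arg(polarity)
  searchSpace <- match.arg(searchSpace)
  cand <- profile@candidates
  if (!length(cand)) stop("profile has no candidates")
  if (searchSpace == "levels") {
    if (is.na(profile@rangeA)) stop("range must be set for level search")
    cand <- seq(as.integer(ceiling(profile@rangeA)),
                as.integer(floor(profile@rangeB)))
  }
  L <- nLevels(img)
  counts <- tabulate(as.numeric(pixels(img)) + 1, nbins = L)
  Hof <- function(t) {
    Hs <- .partitionEntropyCounts(counts, t)
    if (is.null(Hs)) 0 else Hs[["low"]] + Hs[["high"]]
  }
  res <- if (exhaustive) .exhaustiveSearch(cand, Hof)
         else .binarySearchIndex(cand, Hof)
  sel <- as.integer(res$selected)
  Hs <- .partitionEntropyCounts(counts, sel)
  if (is.null(Hs)) stop("degenerate threshold: empty partition at ", sel)
  parts <- if (polarity == "dark")
    c(foreground = Hs[["low"]], background = Hs[["high"]])
  else
    c(foreground = Hs[["high"]], background = Hs[["low"]])
  new("ThresholdSearchTrace", iterations = res$trace, selected = sel,
      Hfinal = unname(Hs[["low"]] + Hs[["high"]]), Hparts = parts)
}

# binary search over the sorted value list; Hof maps a value to its entropy
.binarySearchIndex <- function(cand, Hof) {
  K <- length(cand)
  trace <- list()
  push <- function(lv, H) trace[[length(trace) + 1L]] <<- c(lv, H)
  lo <- 1L; hi <- K
  if (K == 1L) {
    push(cand[1L], Hof(cand[1L]))
  } else {
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      Hm <- Hof(cand[mid]); Hm1 <- Hof(cand[mid + 1L])
      push(cand[mid], Hm); push(cand[mid + 1L], Hm1)
      if (Hm > Hm1) hi <- mid else lo <- mid + 1L
    }
  }
  tr <- do.call(rbind, trace)
  list(selected = cand[lo],
       trace = data.frame(iteration = seq_len(nrow(tr)), level = tr[, 1],
                          H = tr[, 2]))
}

.exhaustiveSearch <- function(cand, Hof) {
  H <- vapply(cand, Hof, numeric(1))
  list(selected = cand[which.max(H)],
       trace = data.frame(iteration = seq_along(cand), level = cand, H = H))
}

#' Write a threshold search trace as CSV
#'
#' Columns \code{iteration, level, H} plus \code{H_normalized} (H divided by
#' the maximum H in the trace), for plotting the optimization path.
#'
#' @param trace a [ThresholdSearchTrace-class].
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeSearchTrace <- function(trace, path) {
  it <- searchTrace(trace)
  it$H_normalized <- if (max(it$H) > 0) it$H / max(it$H) else it$H
  utils::write.csv(it, path, row.names = FALSE)
  invisible(path)
}
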