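#' Counting accuracy against a ground-truth count
#'
#' \code{100 * (1 - |count - truth| / truth)}, in percent. Reported to 2
#' decimals, truncated toward zero so agreement is never overstated (the
#' convention the companion relative error does not share; see
#' [relativeError()]).
#'
#' @param countMethod particle count produced by a segmentation method.
#' @param countTruth ground-truth particle count (> 0).
#' @return Accuracy in percent, 2 decimals.
#' @examples
#' countingAccuracy(997, 1028)
#' @export
countingAccuracy <- function(countMethod, countTruth) {
  if (countTruth <= 0) stop("ground-truth count must be > 0")
  acc <- 100 * (1 - abs(countMethod - countTruth) / countTruth)
  # guard against values an ulp below the 2-decimal grid before truncating
  trunc(acc * 100 + sign(acc) * 1e-9) / 100
}

#' Relative error against a manual reference count
#'
#' \code{|count - manual| / manual * 100}, in percent, rounded half-up to 2
#' decimals. Used when no ground truth exists and expert manual counting is
#' the reference.
#'
#' @param countSeg particle count produced by a segmentation method.
#' @param countManual manual reference count (> 0).
#' @return Relative error in percent, 2 decimals.
#' @examples
#' relativeError(19934, 20362)
#' @export
relativeError <- function(countSeg, countManual) {
  if (countManual <= 0) stop("manual count must be > 0")
  re <- 100 * abs(countSeg - countManual) / countManual
  floor(re * 100 + 0.5) / 100
}

#' Grid specification for grid-cell counting
#'
#' @param cellSize tile side length in pixels, chosen close to one particle
#'   diameter (>= 2).
#' @param origin integer c(row, col) offset of the grid, 0-based.
#' @param coverageFrac a tile counts when its foreground fraction is
#'   strictly greater than this (default 0.5, i.e. "more than 50%").
#' @return A validated list of class \code{"GridSpec"}.
#' @export
gridSpec <- function(cellSize = 10L, origin = c(0L, 0L),
                     coverageFrac = 0.5) {
  cellSize <- as.integer(cellSize)
  if (cellSize < 2L) stop("cellSize must be >= 2")
  if (coverageFrac <= 0 || coverageFrac > 1)
    stop("coverageFrac must be in (0, 1]")
  structure(list(cellSize = cellSize, origin = as.integer(origin),
                 coverageFrac = coverageFrac), class = "GridSpec")
}

#' Count particles by grid cells
#'
#' Overlays a square grid of particle-diameter-sized tiles and counts the
#' tiles whose foreground coverage exceeds the coverage fraction. This is how
#' particles inside dense aggregates are counted, where connected components
#' would see one aggregate as one particle. Partial border tiles participate
#' with their actual (smaller) area.
#'
#' @param mask integer 0/1 matrix.
#' @param grid a [gridSpec()].
#' @return Number of covered tiles.
#' @export
gridCount <- function(mask, grid = gridSpec()) {
  stopifnot(is.matrix(mask), all(mask %in% c(0L, 1L)),
            inherits(grid, "GridSpec"))
  cs <- grid$cellSize
  if (cs > min(dim(mask))) stop("cellSize larger than the image")
  nr <- nrow(mask); nc <- ncol(mask)
  # tile index per pixel; the origin shifts the grid, border tiles partial
  ri <- ((seq_len(nr) - 1L - grid$origin[1]) %/% cs)
  ci <- ((seq_len(nc) - 1L - grid$origin[2]) %/% cs)
  tile <- outer(ri - min(ri), (ci - min(ci)) * (max(ri) - min(ri) + 1L), "+")
  fg <- tapply(as.integer(mask), tile, sum)
  area <- tapply(rep(1L, length(mask)), tile, sum)
  sum(fg / area > grid$coverageFrac)
}

#' Count particles in a segmentation result
#'
#' Dispatch between component counting (isolated particles) and grid-cell
#' counting (dense aggregates).
#'
#' @param result a [SegmentationResult-class].
#' @param mode \code{"components"} or \code{"grid"}.
#' @param grid a [gridSpec()], required for grid mode.
#' @param scanAlignments for grid mode, additionally sweep a 3 x 3 set of
#'   grid origins and report min/median/max (the grid alignment is otherwise
#'   arbitrary).
#' @return Particle count; with \code{scanAlignments}, a named vector
#'   \code{c(count=, min=, median=, max=)} where \code{count} is at the
#'   requested origin.
#' @export
countParticles <- function(result, mode = c("components", "grid"),
                           grid = NULL, scanAlignments = FALSE) {
  stopifnot(is(result, "SegmentationResult"))
  mode <- match.arg(mode)
  if (mode == "components") return(nComponents(result))
  if (is.null(grid)) stop("grid mode requires a gridSpec")
  base <- gridCount(segMask(result), grid)
  if (!scanAlignments) return(base)
  step <- max(1L, grid$cellSize %/% 3L)
  counts <- vapply(0:8, function(k) {
    g <- gridSpec(grid$cellSize,
                  origin = grid$origin + c(k %/% 3L, k %% 3L) * step,
                  coverageFrac = grid$coverageFrac)
    gridCount(segMask(result), g)
  }, numeric(1))
  c(count = base, min = min(counts), median = stats::median(counts),
    max = max(counts))
}

#' Tabulate method counts and scores in the comparison-table layout
#'
#' Builds a data.frame with columns \code{method}, \code{count},
#' \code{score}, \code{score_kind}: accuracy when the reference is a ground
#' truth, relative error when it is a manual count.
#'
#' @param counts named numeric vector of per-method particle counts.
#' @param reference reference count.
#' @param referenceKind \code{"truth"} or \code{"manual"}.
#' @return data.frame, one row per method plus a leading reference row.
#' @export
countReport <- function(counts, reference,
                        referenceKind = c("truth", "manual")) {
  referenceKind <- match.arg(referenceKind)
  if (referenceKind == "truth") {
    score <- vapply(counts, countingAccuracy, numeric(1),
                    countTruth = reference)
    data.frame(method = c("Ground truth", names(counts)),
               count = c(reference, unname(counts)),
               score = c(100, unname(score)),
               score_kind = "accuracy")
  } else {
    score <- vapply(counts, relativeError, numeric(1),
                    countManual = reference)
    data.frame(method = c("Manual counting", names(counts)),
               count = c(reference, unname(counts)),
               score = c(0, unname(score)),
               score_kind = "relative_error")
  }
}
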