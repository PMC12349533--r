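## Canny contour extraction and the banded contour-point similarity.

#' Extract Canny contour points
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression and
#' hysteresis. When `thresholds` is `NULL` the hysteresis thresholds are set
#' automatically; the default rule puts them at fractions `autoParams` of the
#' maximum gradient magnitude, which is robust to background noise because
#' noise gradients sit far below the strongest anatomy edges. The alternative
#' `"quantile"` rule uses the `autoParams` percentiles of the positive
#' gradient magnitudes; it adapts to low-contrast images but admits noise
#' edges when true edges occupy less than the top decile. Points are returned
#' in row-major scan order.
#'
#' @param image a [Radiograph-class] or numeric matrix (at least 3 x 3).
#' @param sigma Gaussian smoothing sigma in pixels (0 disables smoothing).
#' @param thresholds numeric(2) `(low, high)` hysteresis thresholds on the
#'   gradient magnitude, or `NULL` for the automatic rule.
#' @param autoRule automatic threshold rule: `"maxFraction"` (default) or
#'   `"quantile"`.
#' @param autoParams numeric(2) parameters of the automatic rule: fractions
#'   of the maximum magnitude (default `c(0.1, 0.2)`) or quantile levels
#'   (conventionally `c(0.7, 0.9)`).
#' @return A [ContourPointSet-class]; a constant image yields an empty set.
#' @examples
#' img <- matrix(0, 32, 32); img[8:24, 8:24] <- 255
#' extractContours(img)
#' @export
extractContours <- function(image, sigma = 1, thresholds = NULL,
                            autoRule = c("maxFraction", "quantile"),
                            autoParams = NULL) {
    autoRule <- match.arg(autoRule)
    if (is.null(autoParams))
        autoParams <- if (autoRule == "maxFraction") c(0.1, 0.2) else c(0.7, 0.9)
    px <- if (is(image, "Radiograph")) image@pixels else image
    if (!is.matrix(px) || nrow(px) < 3 || ncol(px) < 3)
        stop("image must be a matrix of at least 3 x 3 pixels")
    .assertFinite(px, "image")
    if (is.null(thresholds)) {
        lo <- -1; hi <- -1
    } else {
        .assertLength(thresholds, 2, "thresholds")
        lo <- thresholds[1]; hi <- thresholds[2]
        if (lo < 0 || hi < lo) stop("thresholds must satisfy 0 <= low <= high")
    }
    edge <- .cppCanny(px, sigma, lo, hi, autoParams[1], autoParams[2],
                      autoRule == "quantile")
    idx <- which(edge, arr.ind = TRUE)
    if (nrow(idx)) idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    ContourPointSet(idx, dim(px))
}

#' Banded match score of a single contour-point distance
#'
#' Scores a reference contour point by the distance `d` (pixels) to its
#' nearest floating contour point: 1 when `d = 0`, `w1` when
#' `0 < d <= aBand`, `w2` when `aBand < d <= bBand`, 0 when `d > bBand`.
#'
#' @param d numeric vector of non-negative distances in pixels.
#' @param bands a [SimilarityBands-class].
#' @return Numeric vector of scores in \[0, 1\], non-increasing in `d`.
#' @examples
#' matchScore(c(0, 1, 2, 4), SimilarityBands())
#' @export
matchScore <- function(d, bands = SimilarityBands()) {
    stopifnot(is(bands, "SimilarityBands"))
    .assertFinite(d, "d")
    if (any(d < 0)) stop("distances must be non-negative")
    ifelse(d == 0, 1,
        ifelse(d <= bands@aBand, bands@w1,
            ifelse(d <= bands@bBand, bands@w2, 0)))
}

#' Contour-point similarity between a reference and a floating contour set
#'
#' For every reference contour point, the nearest floating contour point is
#' searched (Euclidean distance) within the square window of half-width
#' `ceiling(bBand)` centered on the same pixel coordinates; the banded
#' [matchScore()] of that distance is accumulated and the mean over all
#' reference points returned. One floating point may serve several reference
#' points; the measure is asymmetric in the two roles.
#'
#' @param reference [ContourPointSet-class] of the reference image (must be
#'   non-empty; an empty reference indicates a broken upstream pipeline and
#'   raises an error).
#' @param floating [ContourPointSet-class] of the floating image; must share
#'   the reference's image shape.
#' @param bands a [SimilarityBands-class].
#' @return Similarity in \[0, 1\]; 1 iff every reference point coincides with
#'   a floating point.
#' @export
contourSimilarity <- function(reference, floating, bands = SimilarityBands()) {
    stopifnot(is(reference, "ContourPointSet"), is(floating, "ContourPointSet"),
              is(bands, "SimilarityBands"))
    if (numPoints(reference) == 0)
        stop("reference contour set is empty; similarity is undefined")
    if (!all(reference@imageDim == floating@imageDim))
        stop("reference and floating images must have the same shape")
    edge <- matrix(FALSE, floating@imageDim[1], floating@imageDim[2])
    if (numPoints(floating))
        edge[floating@points] <- TRUE
    .cppContourSimilarity(reference@points, edge, bands@aBand, bands@bBand,
                          bands@w1, bands@w2)
}

#' Composite dual-view similarity
#'
#' Weighted sum of the frontal and lateral contour similarities,
#' `wf * simF + wl * simL`, with the frontal weight strictly larger.
#'
#' @param simF,simL frontal and lateral similarities in \[0, 1\].
#' @param weights a [CompositeWeights-class].
#' @return The composite similarity, bounded by `wf + wl`.
#' @examples
#' compositeSimilarity(0.8, 0.5, CompositeWeights(0.6, 0.4))  # 0.68
#' @export
compositeSimilarity <- function(simF, simL, weights = CompositeWeights()) {
    stopifnot(is(weights, "CompositeWeights"))
    .assertFinite(c(simF, simL), "similarities")
    if (simF < 0 || simF > 1 || simL < 0 || simL > 1)
        stop("similarities must lie in [0, 1]")
    weights@wf * simF + weights@wl * simL
}

#' Write contour points as CSV
#'
#' Two columns (row, col), 1-based pixel coordinates.
#'
#' @param contours a [ContourPointSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeContours <- function(contours, path) {
    stopifnot(is(contours, "ContourPointSet"))
    write.csv(as.data.frame(contours@points), path, row.names = FALSE)
    invisible(path)
}
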