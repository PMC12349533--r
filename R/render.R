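## DRR generation: projection geometry, trilinear sampling, ray-cast rendering.

#' Default frontal/lateral projection geometry
#'
#' The frontal setup aims the ray bundle along +Z: the point source sits at
#' `isocenter - (0, 0, sourceToIso)` and the detector center at
#' `isocenter + (0, 0, isoToDetector)`, with image columns along +X and rows
#' along -Y. The lateral geometry is the frontal one carried through the
#' inverse of `transMat` (the matrix that moves the volume into the lateral
#' view), so with the default [defaultTransMat()] the lateral source lands on
#' the +X axis at the same radius. Rendering with the lateral geometry is
#' mathematically identical to rendering the volume posed by
#' `composeLateral(frontalMat, transMat)` with the frontal geometry.
#'
#' @param view `"frontal"` or `"lateral"`.
#' @param sourceToIso source-to-isocenter distance, mm.
#' @param isoToDetector isocenter-to-detector distance, mm.
#' @param detectorSize integer(2) (rows, cols) in pixels.
#' @param pixelSpacing detector pixel pitch, mm.
#' @param stepSize ray sampling step, mm (`NA`: renderer default, half the
#'   smallest voxel spacing).
#' @param isocenter numeric(3) world isocenter, mm.
#' @param transMat frontal-to-lateral [RigidTransform-class].
#' @return A [ProjectionGeometry-class].
#' @examples
#' makeDefaultGeometry("frontal")
#' makeDefaultGeometry("lateral")
#' @export
makeDefaultGeometry <- function(view = c("frontal", "lateral"),
                                sourceToIso = 1000, isoToDetector = 200,
                                detectorSize = c(256L, 256L), pixelSpacing = 1,
                                stepSize = NA_real_, isocenter = c(0, 0, 0),
                                transMat = defaultTransMat()) {
    view <- match.arg(view)
    if (sourceToIso <= 0 || isoToDetector <= 0)
        stop("source-to-isocenter and isocenter-to-detector distances must be positive")
    geom <- ProjectionGeometry(
        source = isocenter + c(0, 0, -sourceToIso),
        detectorCenter = isocenter + c(0, 0, isoToDetector),
        detectorU = c(1, 0, 0), detectorV = c(0, -1, 0),
        detectorSize = detectorSize, pixelSpacing = pixelSpacing,
        stepSize = stepSize)
    if (view == "lateral")
        geom <- transformGeometry(geom, rigidInverse(transMat))
    geom
}

#' Carry a projection geometry through a rigid transform
#'
#' Positions (source, detector center) are transformed as points; the
#' detector axes as directions.
#'
#' @param geometry a [ProjectionGeometry-class].
#' @param transform a [RigidTransform-class].
#' @return The transformed [ProjectionGeometry-class].
#' @export
transformGeometry <- function(geometry, transform) {
    stopifnot(is(geometry, "ProjectionGeometry"), is(transform, "RigidTransform"))
    R <- transform@matrix[1:3, 1:3]
    ProjectionGeometry(
        source = applyTransform(transform, geometry@source),
        detectorCenter = applyTransform(transform, geometry@detectorCenter),
        detectorU = drop(R %*% geometry@detectorU),
        detectorV = drop(R %*% geometry@detectorV),
        detectorSize = geometry@detectorSize,
        pixelSpacing = geometry@pixelSpacing,
        stepSize = geometry@stepSize)
}

#' Trilinear interpolation of a volume at world points
#'
#' Interpolates the 8 voxels surrounding each point; points outside the
#' volume's support return 0 (air).
#'
#' @param volume a [CTVolume-class].
#' @param points numeric(3) or N x 3 matrix of world coordinates (mm).
#' @return Numeric vector of interpolated values.
#' @export
sampleTrilinear <- function(volume, points) {
    stopifnot(is(volume, "CTVolume"))
    if (!is.matrix(points)) points <- matrix(points, ncol = 3)
    .assertFinite(points, "points")
    .cppSampleTrilinear(as.numeric(volume@voxels), dim(volume@voxels),
                        volume@spacing, volume@origin, points)
}

.resolveStep <- function(geometry, volume) {
    s <- geometry@stepSize
    if (is.na(s)) s <- min(volume@spacing) / 2
    s
}

.poseToMatrixArg <- function(pose, volume) {
    if (is(pose, "RigidTransform")) return(pose)
    if (is(pose, "Pose")) return(poseMatrix(pose, center = volumeCenter(volume)))
    stop("pose must be a Pose or RigidTransform")
}

#' Render a digitally reconstructed radiograph
#'
#' Casts one ray per detector pixel from the source through the pixel center,
#' pulls uniformly spaced sample points back into the posed volume's frame,
#' and accumulates `step * sum(trilinear samples)` as a Riemann approximation
#' of the line integral. With `normalize = TRUE` the accumulation image is
#' mapped linearly (min-max) onto \[0, 255\] grayscale.
#'
#' The pose moves the volume in world space; a [Pose-class] is converted with
#' [poseMatrix()] about the volume center, and a [RigidTransform-class] is
#' used as-is (e.g. a lateral matrix from [composeLateral()]).
#'
#' @param volume a [CTVolume-class].
#' @param pose a [Pose-class] or [RigidTransform-class].
#' @param geometry a [ProjectionGeometry-class].
#' @param normalize map the accumulation linearly onto \[0, 255\]?
#' @return A [Radiograph-class]. If no ray intersects the volume a warning is
#'   raised and the image is all zero.
#' @examples
#' vol <- CTVolume(array(1, c(32, 32, 32)))
#' geo <- makeDefaultGeometry("frontal", detectorSize = c(64, 64))
#' drr <- renderDRR(vol, Pose(), geo, normalize = FALSE)
#' @export
renderDRR <- function(volume, pose, geometry, normalize = TRUE) {
    stopifnot(is(volume, "CTVolume"), is(geometry, "ProjectionGeometry"))
    mat <- .poseToMatrixArg(pose, volume)
    inv <- rigidInverse(mat)@matrix
    step <- .resolveStep(geometry, volume)
    res <- .cppRenderDRR(as.numeric(volume@voxels), dim(volume@voxels),
                         volume@spacing, volume@origin, inv,
                         geometry@source, geometry@detectorCenter,
                         geometry@detectorU, geometry@detectorV,
                         geometry@detectorSize[1], geometry@detectorSize[2],
                         geometry@pixelSpacing, step)
    if (res$raysHit == 0)
        warning("no ray intersects the volume; returning an all-zero image")
    img <- res$image
    if (normalize) img <- toGrayscale(img)
    Radiograph(img, pixelSpacing = geometry@pixelSpacing)
}

#' Min-max grayscale conversion
#'
#' Linearly maps a matrix onto \[0, 255\]; a constant matrix maps to all
#' zeros.
#'
#' @param pixels numeric matrix.
#' @return Numeric matrix in \[0, 255\].
#' @export
toGrayscale <- function(pixels) {
    rng <- range(pixels)
    if (rng[2] <= rng[1]) return(matrix(0, nrow(pixels), ncol(pixels)))
    (pixels - rng[1]) / (rng[2] - rng[1]) * 255
}

#' Render a batch of poses
#'
#' Renders one DRR per pose with identical semantics to repeated
#' [renderDRR()] calls (order-preserving, bit-identical accumulations). All
#' poses are validated upfront; an invalid entry aborts the whole batch
#' naming its index.
#'
#' @param volume a [CTVolume-class].
#' @param poses list of [Pose-class] / [RigidTransform-class] objects (may be
#'   empty).
#' @param geometry a [ProjectionGeometry-class].
#' @param normalize passed to [renderDRR()].
#' @return A list of [Radiograph-class] objects, same order as `poses`.
#' @export
renderBatch <- function(volume, poses, geometry, normalize = TRUE) {
    stopifnot(is.list(poses))
    for (k in seq_along(poses)) {
        ok <- tryCatch({
            .poseToMatrixArg(poses[[k]], volume)
            TRUE
        }, error = function(e) FALSE)
        if (!ok)
            stop("invalid pose at index ", k, " in batch")
    }
    lapply(poses, function(p) renderDRR(volume, p, geometry, normalize))
}
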