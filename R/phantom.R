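## Procedural CT phantom and simulated radiograph-pair fixtures.

## world coordinates of all voxel centers along one axis
.axisCoords <- function(spec, k) {
    origin <- -spec@spacing * (spec@dim - 1) / 2
    origin[k] + spec@spacing[k] * (seq_len(spec@dim[k]) - 1)
}

.primitiveMask <- function(spec, prim) {
    x <- .axisCoords(spec, 1) - prim$center[1]
    y <- .axisCoords(spec, 2) - prim$center[2]
    z <- .axisCoords(spec, 3) - prim$center[3]
    d <- spec@dim
    X <- array(rep(x, times = d[2] * d[3]), d)
    Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
    Z <- array(rep(z, each = d[1] * d[2]), d)
    switch(prim$type,
        ellipsoid = (X / prim$semiAxes[1])^2 + (Y / prim$semiAxes[2])^2 +
            (Z / prim$semiAxes[3])^2 <= 1,
        cylinder = {
            ax <- match(prim$axis, c("x", "y", "z"))
            along <- list(X, Y, Z)[[ax]]
            perp <- list(X, Y, Z)[-ax]
            (perp[[1]]^2 + perp[[2]]^2 <= prim$radius^2) &
                abs(along) <= prim$halfLength
        },
        box = abs(X) <= prim$halfWidths[1] & abs(Y) <= prim$halfWidths[2] &
            abs(Z) <= prim$halfWidths[3],
        stop("unknown primitive type '", prim$type, "'"))
}

#' Rasterize a phantom specification into a CT volume
#'
#' Fills the volume with the background intensity, rasterizes the primitives
#' in order (the last one wins on overlap, evaluated at voxel centers) and
#' adds seeded Gaussian noise when `noiseSd > 0`. The volume is centered on
#' the world origin. Deterministic for a fixed spec.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [CTVolume-class].
#' @examples
#' spec <- PhantomSpec(dim = 32, primitives = list(
#'     list(type = "ellipsoid", center = c(0, 0, 0), semiAxes = c(8, 10, 6),
#'          intensity = 300)))
#' vol <- generatePhantomVolume(spec)
#' @export
generatePhantomVolume <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    vox <- array(spec@background, spec@dim)
    for (prim in spec@primitives)
        vox[.primitiveMask(spec, prim)] <- prim$intensity
    if (spec@noiseSd > 0) {
        set.seed(deriveSeed(spec@seed, "volume-noise"))
        vox <- vox + array(rnorm(prod(spec@dim), sd = spec@noiseSd), spec@dim)
    }
    CTVolume(vox, spacing = spec@spacing)
}

#' Default spine-like phantom
#'
#' A stack of four bright cylinders (bone at three times the soft-tissue
#' background) along the world Y axis -- the patient's longitudinal axis --
#' with a thin posterior box as a spinous-process analogue. The box breaks
#' the rotational symmetry about the long axis, without which the Y rotation
#' would be unrecoverable from projections. 96 mm cube at 1 mm voxels.
#'
#' @param seed seed for the optional voxel noise stream.
#' @param noiseSd voxel noise standard deviation (default 0, noiseless).
#' @return A [PhantomSpec-class].
#' @export
defaultPhantomSpec <- function(seed = 1, noiseSd = 0) {
    bone <- 300
    cyl <- lapply(c(-33, -11, 11, 33), function(cy)
        list(type = "cylinder", center = c(0, cy, 0), axis = "y",
             radius = 12, halfLength = 9, intensity = bone))
    box <- list(list(type = "box", center = c(0, 0, 17),
                     halfWidths = c(3, 42, 5), intensity = bone))
    PhantomSpec(dim = c(96L, 96L, 96L), spacing = c(1, 1, 1),
                background = 100, noiseSd = noiseSd,
                primitives = c(cyl, box), seed = seed)
}

#' Render the lateral DRR of a posed volume
#'
#' Shared by fixture generation and the registration objective so both sides
#' produce bit-identical images: the lateral view is rendered with the
#' frontal camera after composing the pose with the frontal-to-lateral
#' transform (`LateralMat = TransMat %*% FrontalMat`).
#'
#' @param volume a [CTVolume-class].
#' @param pose a [Pose-class] or frontal [RigidTransform-class].
#' @param geometry the frontal [ProjectionGeometry-class].
#' @param transMat the frontal-to-lateral [RigidTransform-class].
#' @param normalize passed to [renderDRR()].
#' @return A [Radiograph-class].
#' @export
renderLateralDRR <- function(volume, pose, geometry,
                             transMat = defaultTransMat(), normalize = TRUE) {
    frontalMat <- .poseToMatrixArg(pose, volume)
    renderDRR(volume, composeLateral(frontalMat, transMat), geometry, normalize)
}

#' Generate a synthetic registration fixture
#'
#' Renders noiseless frontal and lateral reference DRRs of the phantom at a
#' known ground-truth pose, then adds seeded Gaussian pixel noise on the
#' 8-bit grayscale (clamped to \[0, 255\]). With `noiseSd = 0` the references
#' are bit-identical to the direct renderer output.
#'
#' @param spec a [PhantomSpec-class].
#' @param truePose the ground-truth [Pose-class].
#' @param geometry the frontal [ProjectionGeometry-class].
#' @param noiseSd pixel noise standard deviation on the 0-255 scale
#'   (default 2).
#' @param seed seed of the pixel-noise stream.
#' @param transMat frontal-to-lateral [RigidTransform-class].
#' @return A [FixtureCase-class].
#' @export
generateFixtureCase <- function(spec, truePose, geometry, noiseSd = 2,
                                seed = 1, transMat = defaultTransMat()) {
    stopifnot(is(spec, "PhantomSpec"), is(truePose, "Pose"),
              is(geometry, "ProjectionGeometry"), noiseSd >= 0)
    volume <- generatePhantomVolume(spec)
    frontal <- renderDRR(volume, truePose, geometry, normalize = TRUE)
    lateral <- renderLateralDRR(volume, truePose, geometry, transMat,
                                normalize = TRUE)
    if (noiseSd > 0) {
        set.seed(deriveSeed(seed, "image-noise"))
        addNoise <- function(img) {
            px <- img@pixels + matrix(rnorm(length(img@pixels), sd = noiseSd),
                                      nrow(img@pixels))
            Radiograph(.clamp(px, 0, 255), img@pixelSpacing)
        }
        frontal <- addNoise(frontal)
        lateral <- addNoise(lateral)
    }
    new("FixtureCase", volume = volume, truePose = truePose,
        frontal = frontal, lateral = lateral, geometry = geometry,
        transMat = transMat, noiseSd = as.numeric(noiseSd),
        seed = as.integer(seed))
}

#' Generate the standard seeded fixture set
#'
#' Draws `n` ground-truth poses with per-axis perturbations uniform in
#' `[-maxShift, maxShift]` mm and `[-maxAngle, maxAngle]` degrees around the
#' zero pose (deterministic per seed), and builds one fixture per pose. This
#' emulates a clinical setting where a manual initial pose is a few mm/deg
#' off the truth and the search box is wider than the perturbation.
#'
#' @param n number of fixtures.
#' @param spec a [PhantomSpec-class].
#' @param geometry the frontal [ProjectionGeometry-class]; the default uses a
#'   128 x 128 detector at 2 mm pitch with 1 mm ray sampling.
#' @param maxShift,maxAngle perturbation half-widths (mm, degrees).
#' @param noiseSd pixel noise sd on the 8-bit scale.
#' @param seed master seed; pose draws and noise streams derive from it.
#' @param transMat frontal-to-lateral transform.
#' @return A list of [FixtureCase-class] objects.
#' @export
makeFixtureSet <- function(n = 10, spec = defaultPhantomSpec(),
                           geometry = makeDefaultGeometry("frontal",
                               detectorSize = c(128L, 128L),
                               pixelSpacing = 2, stepSize = 1),
                           maxShift = 4, maxAngle = 4, noiseSd = 2, seed = 1,
                           transMat = defaultTransMat()) {
    stopifnot(n >= 1)
    set.seed(deriveSeed(seed, "fixture-poses"))
    poses <- replicate(n, {
        v <- c(runif(3, -maxShift, maxShift), runif(3, -maxAngle, maxAngle))
        poseFromVector(v)
    }, simplify = FALSE)
    lapply(seq_len(n), function(k)
        generateFixtureCase(spec, poses[[k]], geometry, noiseSd = noiseSd,
                            seed = deriveSeed(seed, paste0("fixture-", k)),
                            transMat = transMat))
}
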