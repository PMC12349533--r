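## Generics and accessor/show methods.

#' @name accessors
#' @title Accessors for DualPoseReg classes
#' @description Slot accessors for the package's S4 classes; user code should
#'   prefer these over direct slot access.
#' @param object an object of the documented class.
#' @return The corresponding slot value.
#' @examples
#' vol <- CTVolume(array(1, c(4, 4, 4)), spacing = 2)
#' voxelSpacing(vol)
#' volumeCenter(vol)
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("volumeOrigin", function(object) standardGeneric("volumeOrigin"))
#' @rdname accessors
#' @export
setGeneric("volumeCenter", function(object) standardGeneric("volumeCenter"))
#' @rdname accessors
#' @export
setGeneric("pixelValues", function(object) standardGeneric("pixelValues"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("translation", function(object) standardGeneric("translation"))
#' @rdname accessors
#' @export
setGeneric("rotationAngles", function(object) standardGeneric("rotationAngles"))
#' @rdname accessors
#' @export
setGeneric("transformMatrix", function(object) standardGeneric("transformMatrix"))
#' @rdname accessors
#' @export
setGeneric("contourPoints", function(object) standardGeneric("contourPoints"))
#' @rdname accessors
#' @export
setGeneric("numPoints", function(object) standardGeneric("numPoints"))
#' @rdname accessors
#' @export
setGeneric("rotationError", function(object) standardGeneric("rotationError"))
#' @rdname accessors
#' @export
setGeneric("translationError", function(object) standardGeneric("translationError"))
#' @rdname accessors
#' @export
setGeneric("bestVector", function(object) standardGeneric("bestVector"))
#' @rdname accessors
#' @export
setGeneric("bestFitness", function(object) standardGeneric("bestFitness"))
#' @rdname accessors
#' @export
setGeneric("fitnessTrace", function(object) standardGeneric("fitnessTrace"))
#' @rdname accessors
#' @export
setGeneric("evaluationCount", function(object) standardGeneric("evaluationCount"))
#' @rdname accessors
#' @export
setGeneric("bestPose", function(object) standardGeneric("bestPose"))
#' @rdname accessors
#' @export
setGeneric("poseSimilarity", function(object) standardGeneric("poseSimilarity"))
#' @rdname accessors
#' @export
setGeneric("registrationError", function(object) standardGeneric("registrationError"))
#' @rdname accessors
#' @export
setGeneric("registrationSuccess", function(object) standardGeneric("registrationSuccess"))
#' @rdname accessors
#' @export
setGeneric("truePose", function(object) standardGeneric("truePose"))
#' @rdname accessors
#' @export
setGeneric("frontalImage", function(object) standardGeneric("frontalImage"))
#' @rdname accessors
#' @export
setGeneric("lateralImage", function(object) standardGeneric("lateralImage"))
#' @rdname accessors
#' @export
setGeneric("fixtureGeometry", function(object) standardGeneric("fixtureGeometry"))
#' @rdname accessors
#' @export
setGeneric("fixtureVolume", function(object) standardGeneric("fixtureVolume"))
#' @rdname accessors
#' @export
setGeneric("configValues", function(object) standardGeneric("configValues"))

#' @rdname accessors
#' @export
setMethod("voxelData", "CTVolume", function(object) object@voxels)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CTVolume", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("volumeOrigin", "CTVolume", function(object) object@origin)
#' @rdname accessors
#' @export
setMethod("volumeCenter", "CTVolume", function(object)
    object@origin + object@spacing * (dim(object@voxels) - 1) / 2)

#' @rdname accessors
#' @export
setMethod("pixelValues", "Radiograph", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("pixelSize", "Radiograph", function(object) object@pixelSpacing)
#' @describeIn accessors image dimensions of a Radiograph.
#' @param x a Radiograph.
#' @export
setMethod("dim", "Radiograph", function(x) dim(x@pixels))

#' @rdname accessors
#' @export
setMethod("translation", "Pose", function(object)
    setNames(object@translation, c("tX", "tY", "tZ")))
#' @rdname accessors
#' @export
setMethod("rotationAngles", "Pose", function(object)
    setNames(object@angles, c("thetaX", "thetaY", "thetaZ")))

#' @rdname accessors
#' @export
setMethod("transformMatrix", "RigidTransform", function(object) object@matrix)

#' @rdname accessors
#' @export
setMethod("contourPoints", "ContourPointSet", function(object) object@points)
#' @rdname accessors
#' @export
setMethod("numPoints", "ContourPointSet", function(object) nrow(object@points))

#' @rdname accessors
#' @export
setMethod("rotationError", "PoseError", function(object)
    setNames(object@rotation, c("X", "Y", "Z")))
#' @rdname accessors
#' @export
setMethod("translationError", "PoseError", function(object)
    setNames(object@translation, c("X", "Y", "Z")))

#' @rdname accessors
#' @export
setMethod("bestVector", "OptimizationResult", function(object) object@bestVector)
#' @rdname accessors
#' @export
setMethod("bestFitness", "OptimizationResult", function(object) object@bestFitness)
#' @rdname accessors
#' @export
setMethod("fitnessTrace", "OptimizationResult", function(object) object@trace)
#' @rdname accessors
#' @export
setMethod("evaluationCount", "OptimizationResult", function(object) object@evaluations)

#' @rdname accessors
#' @export
setMethod("bestPose", "RegistrationResult", function(object) object@bestPose)
#' @rdname accessors
#' @export
setMethod("poseSimilarity", "RegistrationResult", function(object) object@similarity)
#' @rdname accessors
#' @export
setMethod("fitnessTrace", "RegistrationResult", function(object) object@trace)
#' @rdname accessors
#' @export
setMethod("evaluationCount", "RegistrationResult", function(object) object@evaluations)
#' @rdname accessors
#' @export
setMethod("registrationError", "RegistrationResult", function(object) object@error)
#' @rdname accessors
#' @export
setMethod("registrationSuccess", "RegistrationResult", function(object) object@success)

#' @rdname accessors
#' @export
setMethod("truePose", "FixtureCase", function(object) object@truePose)
#' @rdname accessors
#' @export
setMethod("frontalImage", "FixtureCase", function(object) object@frontal)
#' @rdname accessors
#' @export
setMethod("lateralImage", "FixtureCase", function(object) object@lateral)
#' @rdname accessors
#' @export
setMethod("fixtureGeometry", "FixtureCase", function(object) object@geometry)
#' @rdname accessors
#' @export
setMethod("fixtureVolume", "FixtureCase", function(object) object@volume)

#' @rdname accessors
#' @export
setMethod("configValues", "RunConfig", function(object) object@values)

## ---- show methods -----------------------------------------------------------

setMethod("show", "CTVolume", function(object) {
    d <- dim(object@voxels)
    cat(sprintf("CTVolume: %d x %d x %d voxels, spacing (%s) mm\n",
                d[1], d[2], d[3],
                paste(format(object@spacing), collapse = ", ")))
    cat(sprintf("  origin (%s) mm, intensity range [%g, %g]\n",
                paste(format(object@origin), collapse = ", "),
                min(object@voxels), max(object@voxels)))
})

setMethod("show", "Radiograph", function(object) {
    d <- dim(object@pixels)
    cat(sprintf("Radiograph: %d x %d px at %g mm/px, range [%g, %g]\n",
                d[1], d[2], object@pixelSpacing,
                min(object@pixels), max(object@pixels)))
})

setMethod("show", "Pose", function(object) {
    cat(sprintf("Pose: t = (%s) mm, theta = (%s) deg\n",
                paste(format(object@translation), collapse = ", "),
                paste(format(object@angles), collapse = ", ")))
})

setMethod("show", "RigidTransform", function(object) {
    cat("RigidTransform:\n")
    print(round(object@matrix, 6))
})

setMethod("show", "PoseError", function(object) {
    cat(sprintf("PoseError: rotation (%s) deg, translation (%s) mm\n",
                paste(format(object@rotation, digits = 4), collapse = ", "),
                paste(format(object@translation, digits = 4), collapse = ", ")))
})

setMethod("show", "ProjectionGeometry", function(object) {
    cat(sprintf("ProjectionGeometry: source (%s), detector %d x %d px at %g mm\n",
                paste(format(object@source), collapse = ", "),
                object@detectorSize[1], object@detectorSize[2],
                object@pixelSpacing))
})

setMethod("show", "ContourPointSet", function(object) {
    cat(sprintf("ContourPointSet: %d points from a %d x %d image\n",
                nrow(object@points), object@imageDim[1], object@imageDim[2]))
})

setMethod("show", "DEConfig", function(object) {
    cat(sprintf(
        "DEConfig: NP = %d, D = %d, Gmax = %d, F %g->%g, CR %g->%g, seed %d\n",
        object@NP, object@D, object@Gmax, object@fFirst, object@fSecond,
        object@crFirst, object@crSecond, object@seed))
})

setMethod("show", "OptimizationResult", function(object) {
    cat(sprintf("OptimizationResult: best fitness %g after %d evaluations\n",
                object@bestFitness, object@evaluations))
    cat("  best vector:", format(object@bestVector, digits = 6), "\n")
})

setMethod("show", "BenchmarkFunction", function(object) {
    cat(sprintf("BenchmarkFunction %s (%s): D = %d, box [%g, %g], optimum %g\n",
                object@name, object@longName, object@D, object@lower,
                object@upper, object@optimum))
})

setMethod("show", "ConvergenceRecord", function(object) {
    cat(sprintf("ConvergenceRecord: %s / %s, seed %d, final best %g\n",
                object@functionName, object@optimizerName, object@seed,
                object@best))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf("PhantomSpec: %s voxels, background %g, %d primitives, noise sd %g\n",
                paste(object@dim, collapse = " x "), object@background,
                length(object@primitives), object@noiseSd))
})

setMethod("show", "FixtureCase", function(object) {
    cat("FixtureCase:\n  ")
    show(object@volume)
    cat("  truth: ")
    show(object@truePose)
    cat(sprintf("  references: %d x %d px, pixel noise sd %g, seed %d\n",
                dim(object@frontal)[1], dim(object@frontal)[2],
                object@noiseSd, object@seed))
})

setMethod("show", "RegistrationConfig", function(object) {
    cat(sprintf("RegistrationConfig: %s mode, NP = %d, Gmax = %d, seed %d\n",
                object@mode, object@NP, object@Gmax, object@seed))
})

setMethod("show", "RegistrationResult", function(object) {
    cat(sprintf("RegistrationResult (%s mode): composite similarity %.4f\n",
                object@mode, object@similarity))
    cat("  ")
    show(object@bestPose)
    if (!is.null(object@error)) {
        cat("  ")
        show(object@error)
        cat(sprintf("  success: %s\n", object@success))
    }
})

setMethod("show", "RunConfig", function(object) {
    cat("RunConfig (effective settings):\n")
    str(object@values, give.attr = FALSE)
})
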