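## S4 class definitions and constructors for the core data types.

## ---- volumes and images -----------------------------------------------------

#' CTVolume: a 3D scalar grid with voxel spacing and world origin
#'
#' Voxel `(i, j, k)` (0-based) sits at world position
#' `origin + spacing * c(i, j, k)`; array dimension 1 is the world X axis,
#' dimension 2 the Y axis, dimension 3 the Z axis. Intensities are used as-is
#' by the renderer (CT numbers are accepted; no attenuation conversion is
#' applied).
#'
#' @slot voxels 3D numeric array of intensities.
#' @slot spacing numeric(3), mm per voxel along each axis.
#' @slot origin numeric(3), world position (mm) of voxel (0, 0, 0).
#' @aliases CTVolume-class
#' @exportClass CTVolume
setClass("CTVolume",
    representation(voxels = "array", spacing = "numeric", origin = "numeric"),
    validity = function(object) {
        d <- dim(object@voxels)
        if (length(d) != 3) return("voxels must be a 3D array")
        if (any(d < 2)) return("all volume dimensions must be >= 2")
        if (length(object@spacing) != 3 || any(!is.finite(object@spacing)) ||
            any(object@spacing <= 0))
            return("spacing must be 3 positive finite values")
        if (length(object@origin) != 3 || any(!is.finite(object@origin)))
            return("origin must be 3 finite values")
        if (any(!is.finite(object@voxels)))
            return("voxel intensities must be finite")
        TRUE
    })

#' Construct a CTVolume
#'
#' @param voxels 3D numeric array.
#' @param spacing numeric(3) voxel spacing in mm (a scalar is recycled).
#' @param origin numeric(3) world origin in mm; default centers the volume
#'   on the world origin, which is also the default rotation isocenter.
#' @return A [CTVolume-class] object.
#' @examples
#' vol <- CTVolume(array(0, c(8, 8, 8)), spacing = 1)
#' volumeCenter(vol)
#' @export
CTVolume <- function(voxels, spacing = c(1, 1, 1), origin = NULL) {
    spacing <- rep_len(as.numeric(spacing), 3)
    if (is.null(origin))
        origin <- -spacing * (dim(voxels) - 1) / 2
    new("CTVolume", voxels = voxels, spacing = spacing,
        origin = as.numeric(origin))
}

#' Radiograph: a 2D grayscale image with pixel spacing
#'
#' Holds either a raw DRR accumulation image (line integrals, unbounded) or a
#' grayscale-converted image with values in \[0, 255\]. Pixel (1, 1) is the
#' top-left corner; rows advance down the detector, columns to the right.
#'
#' @slot pixels numeric matrix.
#' @slot pixelSpacing numeric(1), mm per pixel.
#' @aliases Radiograph-class
#' @exportClass Radiograph
setClass("Radiograph",
    representation(pixels = "matrix", pixelSpacing = "numeric"),
    validity = function(object) {
        if (!is.numeric(object@pixels)) return("pixels must be numeric")
        if (any(!is.finite(object@pixels))) return("pixel values must be finite")
        if (length(object@pixelSpacing) != 1 || !is.finite(object@pixelSpacing) ||
            object@pixelSpacing <= 0)
            return("pixelSpacing must be a single positive value")
        TRUE
    })

#' @rdname Radiograph-class
#' @param pixels numeric matrix of pixel values.
#' @param pixelSpacing mm per pixel.
#' @return A [Radiograph-class] object.
#' @export
Radiograph <- function(pixels, pixelSpacing = 1) {
    new("Radiograph", pixels = pixels, pixelSpacing = as.numeric(pixelSpacing))
}

## ---- pose and transforms ----------------------------------------------------

#' Pose: six-degree-of-freedom rigid pose parameters
#'
#' Translations in mm along the world X, Y, Z axes and rotations in degrees
#' about those axes. Angles are stored wrapped into (-180, 180].
#'
#' @slot translation numeric(3), (tX, tY, tZ) in mm.
#' @slot angles numeric(3), (thetaX, thetaY, thetaZ) in degrees.
#' @aliases Pose-class
#' @exportClass Pose
setClass("Pose",
    representation(translation = "numeric", angles = "numeric"),
    validity = function(object) {
        if (length(object@translation) != 3 || any(!is.finite(object@translation)))
            return("translation must be 3 finite values")
        if (length(object@angles) != 3 || any(!is.finite(object@angles)))
            return("angles must be 3 finite values")
        if (any(object@angles <= -180 | object@angles > 180))
            return("angles must lie in (-180, 180]")
        TRUE
    })

#' Construct a Pose
#'
#' @param tX,tY,tZ translations in mm.
#' @param thetaX,thetaY,thetaZ rotations in degrees about the world axes;
#'   values outside (-180, 180] are wrapped.
#' @return A [Pose-class] object.
#' @examples
#' Pose(tZ = 4, thetaY = 95)
#' @export
Pose <- function(tX = 0, tY = 0, tZ = 0, thetaX = 0, thetaY = 0, thetaZ = 0) {
    tr <- c(tX, tY, tZ)
    an <- c(thetaX, thetaY, thetaZ)
    .assertFinite(tr, "translation")
    .assertFinite(an, "angles")
    new("Pose", translation = as.numeric(tr), angles = wrapAngle(as.numeric(an)))
}

#' RigidTransform: 4x4 homogeneous rigid transform
#'
#' The rotation block must be orthonormal with determinant +1 and the last
#' row (0, 0, 0, 1).
#'
#' @slot matrix 4x4 numeric matrix.
#' @aliases RigidTransform-class
#' @exportClass RigidTransform
setClass("RigidTransform",
    representation(matrix = "matrix"),
    validity = function(object) {
        m <- object@matrix
        if (!all(dim(m) == c(4, 4))) return("matrix must be 4x4")
        if (any(!is.finite(m))) return("matrix must be finite")
        if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
            return("last row must be (0, 0, 0, 1)")
        R <- m[1:3, 1:3]
        if (max(abs(crossprod(R) - diag(3))) > 1e-9)
            return("rotation block must be orthonormal (R'R = I within 1e-9)")
        if (abs(det(R) - 1) > 1e-9)
            return("rotation block must have determinant +1")
        TRUE
    })

#' @rdname RigidTransform-class
#' @param matrix a 4x4 numeric matrix.
#' @return A [RigidTransform-class] object.
#' @export
RigidTransform <- function(matrix = diag(4)) {
    new("RigidTransform", matrix = unname(matrix))
}

#' PoseError: per-axis pose recovery errors
#'
#' Component-wise absolute differences between an estimated and a true pose;
#' rotation errors are wrapped to the shorter arc and lie in \[0, 180\].
#'
#' @slot rotation numeric(3), degrees (X, Y, Z).
#' @slot translation numeric(3), mm (X, Y, Z).
#' @aliases PoseError-class
#' @exportClass PoseError
setClass("PoseError",
    representation(rotation = "numeric", translation = "numeric"),
    validity = function(object) {
        if (length(object@rotation) != 3 || any(!is.finite(object@rotation)) ||
            any(object@rotation < 0) || any(object@rotation > 180))
            return("rotation errors must lie in [0, 180]")
        if (length(object@translation) != 3 ||
            any(!is.finite(object@translation)) || any(object@translation < 0))
            return("translation errors must be non-negative")
        TRUE
    })

## ---- projection geometry ----------------------------------------------------

#' ProjectionGeometry: point source plus detector plane
#'
#' @slot source numeric(3), source position in mm.
#' @slot detectorCenter numeric(3), detector center in mm.
#' @slot detectorU numeric(3), unit vector along detector columns.
#' @slot detectorV numeric(3), unit vector along detector rows.
#' @slot detectorSize integer(2), (rows, cols) in pixels.
#' @slot pixelSpacing numeric(1), mm per detector pixel.
#' @slot stepSize numeric(1), mm between ray samples; `NA` defers to the
#'   renderer default (half the smallest voxel spacing).
#' @aliases ProjectionGeometry-class
#' @exportClass ProjectionGeometry
setClass("ProjectionGeometry",
    representation(source = "numeric", detectorCenter = "numeric",
                   detectorU = "numeric", detectorV = "numeric",
                   detectorSize = "integer", pixelSpacing = "numeric",
                   stepSize = "numeric"),
    validity = function(object) {
        for (nm in c("source", "detectorCenter", "detectorU", "detectorV"))
            if (length(slot(object, nm)) != 3 || any(!is.finite(slot(object, nm))))
                return(paste(nm, "must be 3 finite values"))
        u <- object@detectorU; v <- object@detectorV
        if (abs(sum(u * u) - 1) > 1e-6 || abs(sum(v * v) - 1) > 1e-6 ||
            abs(sum(u * v)) > 1e-6)
            return("detector axes must be orthonormal")
        n <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
               u[1] * v[2] - u[2] * v[1])
        if (abs(sum((object@source - object@detectorCenter) * n)) < 1e-6)
            return("source must not lie on the detector plane")
        if (length(object@detectorSize) != 2 || any(object@detectorSize < 1))
            return("detectorSize must be two positive integers")
        if (length(object@pixelSpacing) != 1 || !is.finite(object@pixelSpacing) ||
            object@pixelSpacing <= 0)
            return("pixelSpacing must be positive")
        if (length(object@stepSize) != 1 ||
            (!is.na(object@stepSize) && object@stepSize <= 0))
            return("stepSize must be positive or NA")
        TRUE
    })

#' @rdname ProjectionGeometry-class
#' @param source,detectorCenter,detectorU,detectorV,detectorSize,pixelSpacing,stepSize
#'   see slots.
#' @return A [ProjectionGeometry-class] object.
#' @export
ProjectionGeometry <- function(source, detectorCenter, detectorU, detectorV,
                               detectorSize = c(256L, 256L), pixelSpacing = 1,
                               stepSize = NA_real_) {
    new("ProjectionGeometry", source = as.numeric(source),
        detectorCenter = as.numeric(detectorCenter),
        detectorU = as.numeric(detectorU), detectorV = as.numeric(detectorV),
        detectorSize = as.integer(detectorSize),
        pixelSpacing = as.numeric(pixelSpacing),
        stepSize = as.numeric(stepSize))
}

## ---- contours and similarity ------------------------------------------------

#' ContourPointSet: Canny contour point coordinates of one image
#'
#' Points are stored as an N x 2 integer matrix of (row, col) pixel
#' coordinates (1-based), in row-major scan order, with the source image
#' shape retained for window searches.
#'
#' @slot points integer matrix, N x 2, columns (row, col).
#' @slot imageDim integer(2), (rows, cols) of the source image.
#' @aliases ContourPointSet-class
#' @exportClass ContourPointSet
setClass("ContourPointSet",
    representation(points = "matrix", imageDim = "integer"),
    validity = function(object) {
        p <- object@points
        if (ncol(p) != 2) return("points must be an N x 2 matrix")
        if (length(object@imageDim) != 2 || any(object@imageDim < 1))
            return("imageDim must be two positive integers")
        if (nrow(p)) {
            if (any(p < 1) || any(p[, 1] > object@imageDim[1]) ||
                any(p[, 2] > object@imageDim[2]))
                return("contour points must lie within the image bounds")
            if (anyDuplicated(p)) return("contour points must be unique")
        }
        TRUE
    })

#' @rdname ContourPointSet-class
#' @param points N x 2 matrix of (row, col) coordinates.
#' @param imageDim integer(2) image shape (rows, cols).
#' @return A [ContourPointSet-class] object.
#' @export
ContourPointSet <- function(points, imageDim) {
    points <- matrix(as.integer(points), ncol = 2,
                     dimnames = list(NULL, c("row", "col")))
    new("ContourPointSet", points = points, imageDim = as.integer(imageDim))
}

#' SimilarityBands: distance bands and weights of the contour match score
#'
#' A contour point at distance d from its nearest counterpart scores 1 when
#' d = 0, `w1` when 0 < d <= `aBand`, `w2` when `aBand` < d <= `bBand`, and 0
#' beyond `bBand` (distances in pixels).
#'
#' @slot aBand inner band radius, pixels.
#' @slot bBand outer band radius, pixels.
#' @slot w1 weight of the inner band.
#' @slot w2 weight of the outer band.
#' @aliases SimilarityBands-class
#' @exportClass SimilarityBands
setClass("SimilarityBands",
    representation(aBand = "numeric", bBand = "numeric",
                   w1 = "numeric", w2 = "numeric"),
    validity = function(object) {
        if (!(object@aBand > 0 && object@bBand > object@aBand))
            return("bands must satisfy 0 < aBand < bBand")
        if (!(object@w1 <= 1 && object@w1 > object@w2 && object@w2 > 0))
            return("weights must satisfy 1 >= w1 > w2 > 0")
        TRUE
    })

#' @rdname SimilarityBands-class
#' @param aBand,bBand,w1,w2 see slots; defaults penalize one-pixel jitter
#'   mildly (w1 = 0.8) and zero out beyond a 7x7 window (bBand = 3).
#' @return A [SimilarityBands-class] object.
#' @export
SimilarityBands <- function(aBand = 1, bBand = 3, w1 = 0.8, w2 = 0.5) {
    new("SimilarityBands", aBand = as.numeric(aBand), bBand = as.numeric(bBand),
        w1 = as.numeric(w1), w2 = as.numeric(w2))
}

#' CompositeWeights: frontal and lateral weights of the composite similarity
#'
#' The frontal view carries more information for registration, so its weight
#' must be strictly larger than the lateral one; with `wf + wl = 1` the
#' composite similarity stays in \[0, 1\].
#'
#' @slot wf frontal weight, in (0, 1).
#' @slot wl lateral weight, in (0, 1).
#' @aliases CompositeWeights-class
#' @exportClass CompositeWeights
setClass("CompositeWeights",
    representation(wf = "numeric", wl = "numeric"),
    validity = function(object) {
        if (!(object@wf > 0 && object@wf < 1 && object@wl > 0 && object@wl < 1))
            return("weights must lie in (0, 1)")
        if (!(object@wf > object@wl))
            return("the frontal weight must exceed the lateral weight (wf > wl)")
        if (object@wf + object@wl > 1 + 1e-12)
            return("weights must satisfy wf + wl <= 1")
        TRUE
    })

#' @rdname CompositeWeights-class
#' @param wf,wl frontal and lateral weights.
#' @return A [CompositeWeights-class] object.
#' @export
CompositeWeights <- function(wf = 0.6, wl = 0.4) {
    new("CompositeWeights", wf = as.numeric(wf), wl = as.numeric(wl))
}

## ---- optimizer --------------------------------------------------------------

#' DEConfig: configuration of the phased differential-evolution optimizer
#'
#' @slot NP population size (>= 6; DE/rand/2 draws 5 distinct donors).
#' @slot D dimensionality.
#' @slot Gmax number of generations.
#' @slot lower,upper numeric(D) box bounds.
#' @slot fFirst,fSecond scale factor F for the first and second stage.
#' @slot crFirst,crSecond crossover rate CR for the two stages; must satisfy
#'   `crFirst > 0.5 > crSecond`.
#' @slot fScale numeric(D) per-dimension multiplier applied to the stage F.
#' @slot seed integer RNG seed.
#' @slot initial numeric matrix (possibly 0-row) of vectors injected into the
#'   initial population, replacing the first rows.
#' @aliases DEConfig-class
#' @exportClass DEConfig
setClass("DEConfig",
    representation(NP = "integer", D = "integer", Gmax = "integer",
                   lower = "numeric", upper = "numeric",
                   fFirst = "numeric", fSecond = "numeric",
                   crFirst = "numeric", crSecond = "numeric",
                   fScale = "numeric", seed = "integer", initial = "matrix"),
    validity = function(object) {
        if (object@NP < 6) return("NP must be >= 6 for DE/rand/2")
        if (object@D < 1) return("D must be >= 1")
        if (object@Gmax < 1) return("Gmax must be >= 1")
        if (length(object@lower) != object@D || length(object@upper) != object@D)
            return("bounds must have length D")
        if (any(!is.finite(object@lower)) || any(!is.finite(object@upper)) ||
            any(object@lower >= object@upper))
            return("bounds must satisfy lower < upper per dimension")
        for (f in c(object@fFirst, object@fSecond))
            if (!(f > 0 && f <= 2)) return("F values must lie in (0, 2]")
        for (cr in c(object@crFirst, object@crSecond))
            if (!(cr >= 0 && cr < 1)) return("CR values must lie in [0, 1)")
        if (!(object@crFirst > 0.5 && object@crSecond < 0.5))
            return("CR schedule must satisfy crFirst > 0.5 > crSecond")
        if (length(object@fScale) != object@D || any(object@fScale <= 0))
            return("fScale must be D positive multipliers")
        if (ncol(object@initial) && ncol(object@initial) != object@D)
            return("initial vectors must have D columns")
        if (nrow(object@initial) > object@NP)
            return("cannot inject more initial vectors than NP")
        TRUE
    })

#' @rdname DEConfig-class
#' @param NP,D,Gmax,lower,upper,fFirst,fSecond,crFirst,crSecond,fScale,seed,initial
#'   see slots. `lower`/`upper` scalars are recycled to length `D`.
#' @return A [DEConfig-class] object.
#' @examples
#' DEConfig(NP = 10, D = 6, Gmax = 50, lower = -10, upper = 10, seed = 1)
#' @export
DEConfig <- function(NP = 10, D, Gmax = 50, lower, upper,
                     fFirst = 0.5, fSecond = 0.8,
                     crFirst = 0.9, crSecond = 0.3,
                     fScale = rep(1, D), seed = 1,
                     initial = matrix(numeric(0), 0, D)) {
    new("DEConfig", NP = as.integer(NP), D = as.integer(D),
        Gmax = as.integer(Gmax),
        lower = rep_len(as.numeric(lower), D), upper = rep_len(as.numeric(upper), D),
        fFirst = as.numeric(fFirst), fSecond = as.numeric(fSecond),
        crFirst = as.numeric(crFirst), crSecond = as.numeric(crSecond),
        fScale = rep_len(as.numeric(fScale), D), seed = as.integer(seed),
        initial = matrix(as.numeric(initial), nrow(initial), D))
}

#' Population: one generation of candidate vectors with fitness values
#'
#' @slot vectors NP x D numeric matrix.
#' @slot fitness numeric(NP) objective values.
#' @slot generation integer generation index (0 = initial population).
#' @slot bestIndex index of the minimal fitness.
#' @aliases Population-class
#' @exportClass Population
setClass("Population",
    representation(vectors = "matrix", fitness = "numeric",
                   generation = "integer", bestIndex = "integer"),
    validity = function(object) {
        if (nrow(object@vectors) != length(object@fitness))
            return("fitness must have one value per vector")
        if (length(object@bestIndex) != 1 ||
            object@bestIndex < 1 || object@bestIndex > length(object@fitness))
            return("bestIndex out of range")
        if (length(object@fitness) &&
            object@fitness[object@bestIndex] > min(object@fitness) + 1e-15)
            return("bestIndex must minimize fitness")
        TRUE
    })

#' OptimizationResult: outcome of a phased-DE run
#'
#' @slot bestVector best parameter vector found.
#' @slot bestFitness its objective value.
#' @slot trace numeric(Gmax) best-so-far fitness after each generation
#'   (non-increasing).
#' @slot evaluations number of objective evaluations (`NP * (Gmax + 1)`).
#' @slot seed the seed the run used.
#' @aliases OptimizationResult-class
#' @exportClass OptimizationResult
setClass("OptimizationResult",
    representation(bestVector = "numeric", bestFitness = "numeric",
                   trace = "numeric", evaluations = "integer",
                   seed = "integer"),
    validity = function(object) {
        if (length(object@trace) &&
            any(diff(object@trace) > 1e-12)) return("trace must be non-increasing")
        if (length(object@trace) &&
            abs(object@bestFitness - object@trace[length(object@trace)]) > 1e-12)
            return("best fitness must equal the last trace entry")
        TRUE
    })

## ---- benchmarks -------------------------------------------------------------

#' BenchmarkFunction: a registered optimizer test function
#'
#' @slot name short identifier (e.g. "F6").
#' @slot longName descriptive name.
#' @slot D canonical dimensionality.
#' @slot lower,upper search box bounds (scalar, same in every dimension).
#' @slot optimum printed theoretical optimal value.
#' @slot minimizer a known global minimizer.
#' @slot fun the evaluator.
#' @aliases BenchmarkFunction-class
#' @exportClass BenchmarkFunction
setClass("BenchmarkFunction",
    representation(name = "character", longName = "character", D = "integer",
                   lower = "numeric", upper = "numeric", optimum = "numeric",
                   minimizer = "numeric", fun = "function"))

#' ConvergenceRecord: one optimizer run on one benchmark function
#'
#' @slot functionName benchmark function id.
#' @slot optimizerName optimizer label.
#' @slot trace per-generation best-so-far fitness.
#' @slot best final best fitness.
#' @slot seed seed of the run.
#' @aliases ConvergenceRecord-class
#' @exportClass ConvergenceRecord
setClass("ConvergenceRecord",
    representation(functionName = "character", optimizerName = "character",
                   trace = "numeric", best = "numeric", seed = "integer"),
    validity = function(object) {
        if (length(object@trace) && any(diff(object@trace) > 1e-12))
            return("trace must be non-increasing")
        TRUE
    })

## ---- phantom fixtures -------------------------------------------------------

#' PhantomSpec: procedural CT phantom description
#'
#' Primitives are lists with a `type` of "ellipsoid" (`center`, `semiAxes`),
#' "cylinder" (`center`, `axis` in "x"/"y"/"z", `radius`, `halfLength`) or
#' "box" (`center`, `halfWidths`), all in mm in the volume's world frame,
#' plus an `intensity` exceeding the background. Later primitives overwrite
#' earlier ones where they overlap.
#'
#' @slot dim integer(3) voxel counts.
#' @slot spacing numeric(3) mm per voxel.
#' @slot background soft-tissue background intensity.
#' @slot noiseSd standard deviation of additive Gaussian voxel noise (0 = none).
#' @slot primitives list of primitive descriptions.
#' @slot seed integer seed for the noise stream.
#' @aliases PhantomSpec-class
#' @exportClass PhantomSpec
setClass("PhantomSpec",
    representation(dim = "integer", spacing = "numeric", background = "numeric",
                   noiseSd = "numeric", primitives = "list", seed = "integer"),
    validity = function(object) {
        if (length(object@dim) != 3 || any(object@dim < 2))
            return("dim must be 3 values >= 2")
        if (length(object@spacing) != 3 || any(object@spacing <= 0))
            return("spacing must be 3 positive values")
        if (object@noiseSd < 0) return("noiseSd must be >= 0")
        half <- object@spacing * (object@dim - 1) / 2
        for (p in object@primitives) {
            if (is.null(p$type) || is.null(p$center) || is.null(p$intensity))
                return("each primitive needs type, center and intensity")
            if (p$intensity <= object@background)
                return("primitive intensities must exceed the background")
            ext <- switch(p$type,
                ellipsoid = p$semiAxes,
                cylinder = {
                    ax <- match(p$axis, c("x", "y", "z"))
                    e <- rep(p$radius, 3); e[ax] <- p$halfLength; e
                },
                box = p$halfWidths,
                return(sprintf("unknown primitive type '%s'", p$type)))
            if (any(abs(p$center) + ext > half + 1e-9))
                return("primitives must fit inside the volume")
        }
        TRUE
    })

#' @rdname PhantomSpec-class
#' @param dim,spacing,background,noiseSd,primitives,seed see slots.
#' @return A [PhantomSpec-class] object.
#' @export
PhantomSpec <- function(dim = c(96L, 96L, 96L), spacing = c(1, 1, 1),
                        background = 100, noiseSd = 0, primitives = list(),
                        seed = 1) {
    new("PhantomSpec", dim = as.integer(rep_len(dim, 3)),
        spacing = as.numeric(rep_len(spacing, 3)),
        background = as.numeric(background), noiseSd = as.numeric(noiseSd),
        primitives = primitives, seed = as.integer(seed))
}

#' FixtureCase: phantom volume plus simulated reference radiograph pair
#'
#' @slot volume the [CTVolume-class] phantom.
#' @slot truePose the ground-truth [Pose-class] used to render the references.
#' @slot frontal,lateral reference [Radiograph-class] images.
#' @slot geometry the frontal [ProjectionGeometry-class].
#' @slot transMat the frontal-to-lateral [RigidTransform-class].
#' @slot noiseSd pixel noise standard deviation (8-bit scale).
#' @slot seed integer seed of the noise realization.
#' @aliases FixtureCase-class
#' @exportClass FixtureCase
setClass("FixtureCase",
    representation(volume = "CTVolume", truePose = "Pose",
                   frontal = "Radiograph", lateral = "Radiograph",
                   geometry = "ProjectionGeometry", transMat = "RigidTransform",
                   noiseSd = "numeric", seed = "integer"))

## ---- registration -----------------------------------------------------------

#' RegistrationConfig: settings of the end-to-end registration driver
#'
#' @slot mode "dual" (frontal + lateral) or "single" (frontal only).
#' @slot initialPose center of the search box.
#' @slot halfWidths numeric(6) per-dimension search half-widths, ordered
#'   (tX, tY, tZ, thetaX, thetaY, thetaZ) in (mm, mm, mm, deg, deg, deg).
#' @slot bands [SimilarityBands-class].
#' @slot weights [CompositeWeights-class].
#' @slot NP,Gmax optimizer population size and generations.
#' @slot fFirst,fSecond,crFirst,crSecond phased DE control parameters.
#' @slot fScale numeric(6) per-dimension F multipliers; default damps the
#'   depth translation tZ (index 3) to 0.8.
#' @slot cannySigma Gaussian smoothing sigma of the edge detector.
#' @slot cannyLow,cannyHigh hysteresis thresholds; `NA` selects automatic
#'   quantile thresholds.
#' @slot includeInitial inject the initial pose into the starting population.
#' @slot aggregateSuccess evaluate the success criterion on error norms
#'   instead of per axis.
#' @slot seed integer seed.
#' @aliases RegistrationConfig-class
#' @exportClass RegistrationConfig
setClass("RegistrationConfig",
    representation(mode = "character", initialPose = "Pose",
                   halfWidths = "numeric", bands = "SimilarityBands",
                   weights = "CompositeWeights", NP = "integer",
                   Gmax = "integer", fFirst = "numeric", fSecond = "numeric",
                   crFirst = "numeric", crSecond = "numeric",
                   fScale = "numeric", cannySigma = "numeric",
                   cannyLow = "numeric", cannyHigh = "numeric",
                   includeInitial = "logical", aggregateSuccess = "logical",
                   seed = "integer"),
    validity = function(object) {
        if (!object@mode %in% c("dual", "single"))
            return("mode must be 'dual' or 'single'")
        if (length(object@halfWidths) != 6 || any(object@halfWidths <= 0))
            return("halfWidths must be 6 positive values")
        if (length(object@fScale) != 6 || any(object@fScale <= 0))
            return("fScale must be 6 positive multipliers")
        if (object@cannySigma < 0) return("cannySigma must be >= 0")
        TRUE
    })

#' @rdname RegistrationConfig-class
#' @param mode,initialPose,halfWidths,bands,weights,NP,Gmax,fFirst,fSecond,crFirst,crSecond,fScale,cannySigma,cannyLow,cannyHigh,includeInitial,aggregateSuccess,seed
#'   see slots.
#' @return A [RegistrationConfig-class] object.
#' @export
RegistrationConfig <- function(mode = c("dual", "single"),
                               initialPose = Pose(),
                               halfWidths = rep(10, 6),
                               bands = SimilarityBands(),
                               weights = CompositeWeights(),
                               NP = 10, Gmax = 50,
                               fFirst = 0.5, fSecond = 0.8,
                               crFirst = 0.9, crSecond = 0.3,
                               fScale = c(1, 1, 0.8, 1, 1, 1),
                               cannySigma = 1, cannyLow = NA_real_,
                               cannyHigh = NA_real_, includeInitial = TRUE,
                               aggregateSuccess = FALSE, seed = 1) {
    new("RegistrationConfig", mode = match.arg(mode), initialPose = initialPose,
        halfWidths = rep_len(as.numeric(halfWidths), 6), bands = bands,
        weights = weights, NP = as.integer(NP), Gmax = as.integer(Gmax),
        fFirst = as.numeric(fFirst), fSecond = as.numeric(fSecond),
        crFirst = as.numeric(crFirst), crSecond = as.numeric(crSecond),
        fScale = rep_len(as.numeric(fScale), 6),
        cannySigma = as.numeric(cannySigma), cannyLow = as.numeric(cannyLow),
        cannyHigh = as.numeric(cannyHigh),
        includeInitial = isTRUE(includeInitial),
        aggregateSuccess = isTRUE(aggregateSuccess), seed = as.integer(seed))
}

#' RegistrationResult: outcome of a registration run
#'
#' @slot bestPose the recovered [Pose-class].
#' @slot similarity composite similarity of the best pose.
#' @slot trace per-generation best composite similarity (non-decreasing).
#' @slot evaluations number of objective evaluations.
#' @slot mode "dual" or "single".
#' @slot error [PoseError-class] versus ground truth, or `NULL`.
#' @slot success logical success flag (`NA` when no truth was supplied).
#' @aliases RegistrationResult-class
#' @exportClass RegistrationResult
setClass("RegistrationResult",
    representation(bestPose = "Pose", similarity = "numeric",
                   trace = "numeric", evaluations = "integer",
                   mode = "character", error = "ANY", success = "logical"))

## ---- run configuration ------------------------------------------------------

#' RunConfig: validated, fully defaulted run configuration
#'
#' Produced by [loadRunConfig()]; holds the effective configuration after
#' schema validation and default materialization. Access the nested values
#' with [configValues()].
#'
#' @slot values named nested list of settings.
#' @aliases RunConfig-class
#' @exportClass RunConfig
setClass("RunConfig", representation(values = "list"))
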