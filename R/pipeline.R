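## End-to-end dual-pose registration: objective assembly, the driver, the
## success criterion and the single-vs-dual comparison harness.

.extractRefContours <- function(image, config, what) {
    thr <- if (is.na(config@cannyLow) || is.na(config@cannyHigh)) NULL
           else c(config@cannyLow, config@cannyHigh)
    ref <- extractContours(image, sigma = config@cannySigma, thresholds = thr)
    if (numPoints(ref) == 0)
        stop("empty reference contour set for the ", what,
             " image; check rendering/normalization settings", call. = FALSE)
    ref
}

#' Composite registration objective
#'
#' Renders the frontal (and, in dual mode, lateral) DRR of the volume at
#' `pose`, extracts the floating contour points and scores them against the
#' precomputed reference contour sets. Dual mode returns the composite
#' similarity `wf * simF + wl * simL`; single mode returns the frontal
#' similarity alone.
#'
#' @param pose a [Pose-class] candidate.
#' @param volume a [CTVolume-class].
#' @param refFrontal reference [ContourPointSet-class] of the frontal
#'   radiograph (precomputed once per run).
#' @param refLateral reference [ContourPointSet-class] of the lateral
#'   radiograph, or `NULL` in single mode.
#' @param geometry the frontal [ProjectionGeometry-class].
#' @param config a [RegistrationConfig-class] (bands, weights, Canny
#'   settings).
#' @param transMat frontal-to-lateral [RigidTransform-class].
#' @return The similarity value; in `[0, 1]` (single) or `[0, wf + wl]`
#'   (dual).
#' @export
registrationObjective <- function(pose, volume, refFrontal, refLateral = NULL,
                                  geometry, config = RegistrationConfig(),
                                  transMat = defaultTransMat()) {
    stopifnot(is(refFrontal, "ContourPointSet"))
    thr <- if (is.na(config@cannyLow) || is.na(config@cannyHigh)) NULL
           else c(config@cannyLow, config@cannyHigh)
    drrF <- renderDRR(volume, pose, geometry, normalize = TRUE)
    cF <- extractContours(drrF, sigma = config@cannySigma, thresholds = thr)
    simF <- if (numPoints(cF) == 0) 0
            else contourSimilarity(refFrontal, cF, config@bands)
    if (is.null(refLateral))
        return(simF)
    drrL <- renderLateralDRR(volume, pose, geometry, transMat,
                             normalize = TRUE)
    cL <- extractContours(drrL, sigma = config@cannySigma, thresholds = thr)
    simL <- if (numPoints(cL) == 0) 0
            else contourSimilarity(refLateral, cL, config@bands)
    compositeSimilarity(simF, simL, config@weights)
}

#' Register a CT volume to one or two radiographs
#'
#' Builds the composite contour objective from the reference images, then
#' maximizes it with the phased differential-evolution optimizer (the
#' optimizer minimizes the negated similarity) over the search box
#' `initialPose +/- halfWidths`. Reference contours are extracted once;
#' floating contours are re-extracted for every candidate pose. Deterministic
#' for a fixed config seed.
#'
#' @param volume a [CTVolume-class].
#' @param frontal frontal reference [Radiograph-class].
#' @param lateral lateral reference [Radiograph-class]; required in dual
#'   mode, ignored in single mode.
#' @param geometry the frontal [ProjectionGeometry-class].
#' @param config a [RegistrationConfig-class].
#' @param transMat frontal-to-lateral [RigidTransform-class].
#' @param truth optional ground-truth [Pose-class]; when given, the result
#'   carries the per-axis [poseError()] and the 3 degree / 3 mm success flag.
#' @return A [RegistrationResult-class].
#' @examples
#' \donttest{
#' fix <- makeFixtureSet(n = 1, spec = defaultPhantomSpec(),
#'     geometry = makeDefaultGeometry("frontal", detectorSize = c(64, 64),
#'                                    pixelSpacing = 4))[[1]]
#' res <- registerPose(fixtureVolume(fix), frontalImage(fix),
#'     lateralImage(fix), fixtureGeometry(fix),
#'     RegistrationConfig(Gmax = 5, seed = 1), truth = truePose(fix))
#' }
#' @export
registerPose <- function(volume, frontal, lateral = NULL, geometry,
                         config = RegistrationConfig(),
                         transMat = defaultTransMat(), truth = NULL) {
    stopifnot(is(volume, "CTVolume"), is(frontal, "Radiograph"),
              is(geometry, "ProjectionGeometry"),
              is(config, "RegistrationConfig"))
    dual <- config@mode == "dual"
    if (dual && !is(lateral, "Radiograph"))
        stop("dual mode requires a lateral reference image")

    refF <- .extractRefContours(frontal, config, "frontal")
    refL <- if (dual) .extractRefContours(lateral, config, "lateral") else NULL
    .dprMessage("reference contours: frontal ", numPoints(refF),
                if (dual) paste0(", lateral ", numPoints(refL)) else "")

    center <- poseAsVector(config@initialPose)
    deCfg <- DEConfig(NP = config@NP, D = 6, Gmax = config@Gmax,
                      lower = center - config@halfWidths,
                      upper = center + config@halfWidths,
                      fFirst = config@fFirst, fSecond = config@fSecond,
                      crFirst = config@crFirst, crSecond = config@crSecond,
                      fScale = config@fScale, seed = config@seed,
                      initial = if (config@includeInitial)
                          matrix(center, 1, 6) else matrix(numeric(0), 0, 6))
    objective <- function(x)
        -registrationObjective(poseFromVector(x), volume, refF, refL,
                               geometry, config, transMat)
    opt <- optimizePDE(objective, deCfg)

    best <- poseFromVector(bestVector(opt))
    err <- if (!is.null(truth)) poseError(best, truth) else NULL
    succ <- if (!is.null(err))
        evaluateSuccess(err, aggregate = config@aggregateSuccess) else NA
    new("RegistrationResult", bestPose = best,
        similarity = -bestFitness(opt), trace = -fitnessTrace(opt),
        evaluations = evaluationCount(opt), mode = config@mode,
        error = err, success = succ)
}

#' Registration success criterion
#'
#' Success requires every per-axis rotation error strictly below
#' `rotationTol` degrees and every translation error strictly below
#' `translationTol` mm (3 and 3 by default). With `aggregate = TRUE` the
#' Euclidean norms of the rotation and translation error vectors are
#' compared to the tolerances instead.
#'
#' @param error a [PoseError-class].
#' @param rotationTol rotation tolerance, degrees.
#' @param translationTol translation tolerance, mm.
#' @param aggregate use error norms instead of per-axis comparison.
#' @return Logical flag.
#' @examples
#' evaluateSuccess(poseError(Pose(tZ = 2.9), Pose()))        # TRUE
#' evaluateSuccess(poseError(Pose(thetaX = 3), Pose()))      # FALSE (strict)
#' @export
evaluateSuccess <- function(error, rotationTol = 3, translationTol = 3,
                            aggregate = FALSE) {
    stopifnot(is(error, "PoseError"))
    if (aggregate)
        sqrt(sum(error@rotation^2)) < rotationTol &&
            sqrt(sum(error@translation^2)) < translationTol
    else
        all(error@rotation < rotationTol) &&
            all(error@translation < translationTol)
}

#' Compare dual-pose against single-pose registration
#'
#' Runs both modes on identical fixtures (same volume, references, search box
#' and optimizer seed per trial) and summarizes per-axis mean errors, success
#' rates and the percent reduction of the mean rotation and translation
#' errors achieved by the dual-pose strategy. Single-view registration
#' under-constrains the depth translation (tZ), which is where the dual view
#' is expected to help most.
#'
#' @param fixtures list of at least two [FixtureCase-class] objects.
#' @param config a [RegistrationConfig-class]; the mode slot is overridden
#'   per run.
#' @param seeds optional integer vector of per-trial optimizer seeds
#'   (default: derived from `config@seed` and the trial index).
#' @return A list with `perTrial` (data.frame of per-axis errors by trial and
#'   mode), `summary` (mean errors and success rate per mode), and
#'   `reductions` (percent reduction, dual vs single, of the mean rotation
#'   and translation errors and of the mean tZ error).
#' @export
compareSingleVsDual <- function(fixtures, config = RegistrationConfig(),
                                seeds = NULL) {
    stopifnot(is.list(fixtures))
    if (length(fixtures) < 2)
        stop("at least two trials are required")
    if (is.null(seeds))
        seeds <- vapply(seq_along(fixtures), function(k)
            deriveSeed(config@seed, paste0("trial-", k)), integer(1))
    stopifnot(length(seeds) == length(fixtures))

    runOne <- function(fix, mode, seed) {
        cfg <- config
        cfg@mode <- mode
        cfg@seed <- as.integer(seed)
        res <- registerPose(fixtureVolume(fix), frontalImage(fix),
                            if (mode == "dual") lateralImage(fix) else NULL,
                            fixtureGeometry(fix), cfg,
                            transMat = fix@transMat, truth = truePose(fix))
        err <- registrationError(res)
        data.frame(mode = mode, seed = seed,
                   rotX = rotationError(err)[["X"]],
                   rotY = rotationError(err)[["Y"]],
                   rotZ = rotationError(err)[["Z"]],
                   tX = translationError(err)[["X"]],
                   tY = translationError(err)[["Y"]],
                   tZ = translationError(err)[["Z"]],
                   success = registrationSuccess(res),
                   similarity = poseSimilarity(res))
    }

    perTrial <- do.call(rbind, lapply(seq_along(fixtures), function(k) {
        cbind(trial = k,
              rbind(runOne(fixtures[[k]], "dual", seeds[k]),
                    runOne(fixtures[[k]], "single", seeds[k])))
    }))

    cols <- c("rotX", "rotY", "rotZ", "tX", "tY", "tZ")
    summarize <- function(mode) {
        sub <- perTrial[perTrial$mode == mode, ]
        means <- colMeans(sub[cols])
        data.frame(mode = mode, t(means),
                   successRate = mean(sub$success))
    }
    summary <- rbind(summarize("dual"), summarize("single"))
    meanRot <- function(mode)
        mean(unlist(perTrial[perTrial$mode == mode, c("rotX", "rotY", "rotZ")]))
    meanTrans <- function(mode)
        mean(unlist(perTrial[perTrial$mode == mode, c("tX", "tY", "tZ")]))
    meanTz <- function(mode) mean(perTrial[perTrial$mode == mode, "tZ"])
    pct <- function(single, dual) 100 * (single - dual) / single
    list(perTrial = perTrial, summary = summary,
         reductions = c(
             rotation = pct(meanRot("single"), meanRot("dual")),
             translation = pct(meanTrans("single"), meanTrans("dual")),
             tZ = pct(meanTz("single"), meanTz("dual"))))
}
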