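## shared noiseless fixture at coarse resolution: fast to render, clean refs
regFixture <- function(pose = Pose(tX = 2, tY = -1, thetaZ = 4), seed = 3)
    generateFixtureCase(quickPhantomSpec(), pose, quickGeometry(),
                        noiseSd = 0, seed = seed)

refSets <- function(fix, config = RegistrationConfig()) {
    thr <- NULL
    list(F = extractContours(pixelValues(frontalImage(fix)),
                             sigma = config@cannySigma, thresholds = thr),
         L = extractContours(pixelValues(lateralImage(fix)),
                             sigma = config@cannySigma, thresholds = thr))
}

test_that("the objective is exact at the truth on self-rendered references", {
    fix <- regFixture()
    cfg <- RegistrationConfig()
    refs <- refSets(fix, cfg)
    vol <- fixtureVolume(fix)

    ## wf + wl = 1 and bit-identical renders give exactly 1
    simDual <- registrationObjective(truePose(fix), vol, refs$F, refs$L,
                                     fixtureGeometry(fix), cfg, fix@transMat)
    expect_identical(simDual, 1)

    ## single mode returns the frontal similarity alone
    simSingle <- registrationObjective(truePose(fix), vol, refs$F, NULL,
                                       fixtureGeometry(fix), cfg,
                                       fix@transMat)
    expect_identical(simSingle, 1)

    ## a displacement far beyond the silhouette diameter pushes every
    ## contour point out of band in both views: an isolated sphere on an
    ## empty background leaves no contour segment to slide along
    sphereSpec <- PhantomSpec(dim = c(48L, 48L, 48L), spacing = c(2, 2, 2),
                              background = 0, seed = 1,
                              primitives = list(
                                  list(type = "ellipsoid",
                                       center = c(0, 0, 0),
                                       semiAxes = c(10, 10, 10),
                                       intensity = 300)))
    sFix <- generateFixtureCase(sphereSpec, Pose(), quickGeometry(),
                                noiseSd = 0, seed = 1)
    sRefs <- refSets(sFix, cfg)
    far <- Pose(tX = 40, tY = 40, tZ = 40)
    expect_equal(registrationObjective(far, fixtureVolume(sFix), sRefs$F,
                                       sRefs$L, fixtureGeometry(sFix), cfg,
                                       sFix@transMat), 0)
})

test_that("registration inputs are validated before optimization", {
    fix <- regFixture()
    cfg <- RegistrationConfig(Gmax = 2, seed = 1)
    expect_error(
        registerPose(fixtureVolume(fix), frontalImage(fix), NULL,
                     fixtureGeometry(fix), cfg, transMat = fix@transMat),
        "lateral")

    flat <- Radiograph(matrix(0, 64, 64), pixelSpacing = 4)
    expect_error(
        registerPose(fixtureVolume(fix), flat, lateralImage(fix),
                     fixtureGeometry(fix), cfg, transMat = fix@transMat),
        "empty reference contour")
})

test_that("success evaluation is strict, per axis and monotone", {
    err <- function(r, t) poseError(poseFromVector(c(t, 0, 0, r, 0, 0)),
                                    Pose())
    expect_true(evaluateSuccess(err(1, 1)))
    expect_true(evaluateSuccess(err(2.9, 2.9)))
    expect_false(evaluateSuccess(err(3, 0)))       # strict "less than"
    expect_false(evaluateSuccess(err(0, 3)))
    ## monotone: shrinking any component never flips success to failure
    expect_true(evaluateSuccess(err(2.9, 0)))
    ## aggregate variant compares error norms
    e <- poseError(poseFromVector(c(2.5, 2.5, 2.5, 0, 0, 0)), Pose())
    expect_true(evaluateSuccess(e))
    expect_false(evaluateSuccess(e, aggregate = TRUE))
})

test_that("an injected truth pose is never replaced (elitist search)", {
    fix <- regFixture()
    cfg <- RegistrationConfig(initialPose = truePose(fix), Gmax = 3,
                              includeInitial = TRUE, seed = 2)
    res <- registerPose(fixtureVolume(fix), frontalImage(fix),
                        lateralImage(fix), fixtureGeometry(fix), cfg,
                        transMat = fix@transMat, truth = truePose(fix))
    ## the truth scores the attainable maximum, so it must survive
    expect_identical(poseSimilarity(res), 1)
    expect_identical(poseAsVector(bestPose(res)),
                     poseAsVector(truePose(fix)))
    expect_true(registrationSuccess(res))
    ## the similarity trace never drops below the injected pose's score
    expect_true(all(fitnessTrace(res) >= 1 - 1e-12))
})

test_that("registration is deterministic per seed and reports its trace", {
    fix <- regFixture()
    cfg <- RegistrationConfig(Gmax = 4, seed = 7, includeInitial = FALSE)
    r1 <- registerPose(fixtureVolume(fix), frontalImage(fix),
                       lateralImage(fix), fixtureGeometry(fix), cfg,
                       transMat = fix@transMat, truth = truePose(fix))
    r2 <- registerPose(fixtureVolume(fix), frontalImage(fix),
                       lateralImage(fix), fixtureGeometry(fix), cfg,
                       transMat = fix@transMat, truth = truePose(fix))
    expect_identical(poseAsVector(bestPose(r1)), poseAsVector(bestPose(r2)))
    expect_identical(fitnessTrace(r1), fitnessTrace(r2))
    expect_length(fitnessTrace(r1), 4)
    ## similarity trace is non-decreasing (elitist optimizer, negated)
    expect_true(all(diff(fitnessTrace(r1)) >= 0))
    expect_equal(evaluationCount(r1), 10L * 5L)
    ## best pose stays inside the search box
    expect_true(all(abs(poseAsVector(bestPose(r1))) <= 10 + 1e-9))
})

test_that("the comparison harness mirrors modes on identical trials", {
    expect_error(compareSingleVsDual(list(regFixture())), "at least two")

    fixtures <- list(regFixture(Pose(tX = 1.5, tZ = 2, thetaZ = 3), seed = 1),
                     regFixture(Pose(tY = -2, tZ = -1.5, thetaY = 2),
                                seed = 2))
    cfg <- RegistrationConfig(Gmax = 6, seed = 5)
    cmp <- compareSingleVsDual(fixtures, cfg)
    expect_equal(nrow(cmp$perTrial), 4)         # 2 trials x 2 modes
    expect_setequal(unique(cmp$perTrial$mode), c("dual", "single"))
    expect_equal(nrow(cmp$summary), 2)
    expect_named(cmp$reductions, c("rotation", "translation", "tZ"))

    ## identical trial lists give identical summaries
    cmp2 <- compareSingleVsDual(fixtures, cfg)
    expect_identical(cmp$perTrial, cmp2$perTrial)
    expect_identical(cmp$reductions, cmp2$reductions)
})
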