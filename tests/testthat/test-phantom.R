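test_that("primitives rasterize exactly at voxel centers", {
    spec <- PhantomSpec(dim = 32, spacing = 1, background = 50, seed = 1,
                        primitives = list(
                            list(type = "ellipsoid", center = c(0, 0, 0),
                                 semiAxes = c(8, 10, 6), intensity = 200)))
    vol <- generatePhantomVolume(spec)
    vox <- voxelData(vol)
    ## classify voxel centers independently
    co <- volumeOrigin(vol)
    x <- co[1] + (0:31); y <- co[2] + (0:31); z <- co[3] + (0:31)
    inside <- outer(outer((x / 8)^2, (y / 10)^2, "+"), (z / 6)^2, "+") <= 1
    expect_true(all(vox[inside] == 200))
    expect_true(all(vox[!inside] == 50))
})

test_that("rasterized volume matches the analytic primitive volume", {
    spec <- PhantomSpec(dim = 64, spacing = 1, background = 0,
                        primitives = list(
                            list(type = "ellipsoid", center = c(0, 0, 0),
                                 semiAxes = c(20, 14, 24), intensity = 10)),
                        seed = 1)
    vol <- generatePhantomVolume(spec)
    count <- sum(voxelData(vol) == 10)
    analytic <- 4 / 3 * pi * 20 * 14 * 24
    expect_lt(abs(count - analytic) / analytic, 0.02)
})

test_that("phantom generation is deterministic per seed", {
    s1 <- PhantomSpec(dim = 24, background = 100, noiseSd = 3, seed = 4,
                      primitives = list(list(type = "box", center = c(0, 0, 0),
                                             halfWidths = c(5, 5, 5),
                                             intensity = 300)))
    v1 <- generatePhantomVolume(s1)
    v2 <- generatePhantomVolume(s1)
    expect_identical(voxelData(v1), voxelData(v2))

    s2 <- PhantomSpec(dim = 24, background = 100, noiseSd = 3, seed = 5,
                      primitives = s1@primitives)
    expect_false(identical(voxelData(v1),
                           voxelData(generatePhantomVolume(s2))))
})

test_that("invalid primitives are rejected", {
    expect_error(PhantomSpec(dim = 24, primitives = list(
        list(type = "ellipsoid", center = c(20, 0, 0),
             semiAxes = c(8, 8, 8), intensity = 300))), "fit inside")
    expect_error(PhantomSpec(dim = 24, background = 100, primitives = list(
        list(type = "box", center = c(0, 0, 0), halfWidths = c(2, 2, 2),
             intensity = 50))), "exceed the background")
    expect_error(PhantomSpec(dim = 24, primitives = list(
        list(type = "pyramid", center = c(0, 0, 0), intensity = 300))),
        "unknown primitive")
})

test_that("noiseless fixtures equal the direct renderer output", {
    spec <- quickPhantomSpec()
    geo <- quickGeometry()
    pose <- Pose(tX = 2, thetaZ = 5)
    fix <- generateFixtureCase(spec, pose, geo, noiseSd = 0, seed = 9)

    vol <- generatePhantomVolume(spec)
    expect_identical(pixelValues(frontalImage(fix)),
                     pixelValues(renderDRR(vol, pose, geo)))
    expect_identical(pixelValues(lateralImage(fix)),
                     pixelValues(renderLateralDRR(vol, pose, geo)))
    expect_identical(poseAsVector(truePose(fix)), poseAsVector(pose))
})

test_that("fixture noise is seeded and clamped to the 8-bit range", {
    spec <- quickPhantomSpec()
    geo <- quickGeometry()
    pose <- Pose()
    f1 <- generateFixtureCase(spec, pose, geo, noiseSd = 2, seed = 1)
    f2 <- generateFixtureCase(spec, pose, geo, noiseSd = 2, seed = 1)
    f3 <- generateFixtureCase(spec, pose, geo, noiseSd = 2, seed = 2)
    expect_identical(pixelValues(frontalImage(f1)),
                     pixelValues(frontalImage(f2)))
    expect_false(identical(pixelValues(frontalImage(f1)),
                           pixelValues(frontalImage(f3))))
    expect_true(all(pixelValues(frontalImage(f1)) >= 0))
    expect_true(all(pixelValues(frontalImage(f1)) <= 255))

    ## different seeds share the same noiseless base
    base <- pixelValues(renderDRR(generatePhantomVolume(spec), pose, geo))
    expect_lt(mean(abs(pixelValues(frontalImage(f3)) - base)), 3 * 2)
})

test_that("the standard fixture set is reproducible and within bounds", {
    set1 <- makeFixtureSet(n = 3, spec = quickPhantomSpec(),
                           geometry = quickGeometry(), seed = 2)
    set2 <- makeFixtureSet(n = 3, spec = quickPhantomSpec(),
                           geometry = quickGeometry(), seed = 2)
    for (k in 1:3) {
        expect_identical(poseAsVector(truePose(set1[[k]])),
                         poseAsVector(truePose(set2[[k]])))
        expect_identical(pixelValues(frontalImage(set1[[k]])),
                         pixelValues(frontalImage(set2[[k]])))
        expect_true(all(abs(poseAsVector(truePose(set1[[k]]))) <= 4))
    }
    ## distinct poses across fixtures
    expect_false(identical(poseAsVector(truePose(set1[[1]])),
                           poseAsVector(truePose(set1[[2]]))))
})
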