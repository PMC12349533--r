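test_that("default geometries echo the configured setup", {
    g <- makeDefaultGeometry("frontal")
    expect_equal(g@source, c(0, 0, -1000))
    expect_equal(g@detectorCenter, c(0, 0, 200))
    expect_equal(g@detectorSize, c(256L, 256L))
    expect_equal(g@pixelSpacing, 1)

    ## lateral view: frontal source carried onto the +X axis, same radius
    gl <- makeDefaultGeometry("lateral")
    expect_equal(gl@source, c(1000, 0, 0), tolerance = 1e-9)
    expect_equal(sqrt(sum(gl@source^2)), 1000, tolerance = 1e-9)

    expect_error(makeDefaultGeometry("frontal", sourceToIso = 0), "positive")
    expect_error(makeDefaultGeometry("frontal", isoToDetector = -5),
                 "positive")
})

test_that("trilinear sampling matches the 8-corner oracle", {
    set.seed(42)
    vox <- array(runif(12 * 14 * 10), c(12, 14, 10))
    vol <- CTVolume(vox, spacing = c(1.5, 1, 2), origin = c(-3, 2, -7))

    ## voxel centers reproduce stored values
    expect_equal(sampleTrilinear(vol, volumeOrigin(vol) +
                                     voxelSpacing(vol) * c(3, 5, 2)),
                 vox[4, 6, 3])

    ## midpoint of two adjacent voxels averages them
    vox2 <- array(0, c(4, 4, 4)); vox2[2, 2, 2] <- 0; vox2[3, 2, 2] <- 10
    v2 <- CTVolume(vox2, spacing = c(1, 1, 1), origin = c(0, 0, 0))
    expect_equal(sampleTrilinear(v2, c(1.5, 1, 1)), 5)

    ## 50 random interior points against the nested-loop oracle
    set.seed(7)
    pts <- cbind(runif(50, -2, 12), runif(50, 3, 14), runif(50, -6, 10))
    got <- sampleTrilinear(vol, pts)
    want <- apply(pts, 1, function(p)
        trilinearOracle(vox, voxelSpacing(vol), volumeOrigin(vol), p))
    expect_equal(got, want, tolerance = 1e-9)

    ## outside the support the volume reads as air
    expect_equal(sampleTrilinear(vol, c(1e4, 0, 0)), 0)
})

test_that("line integrals match analytic chords through a homogeneous cube", {
    vol <- unitCubeVolume()          # support [-32, 32]^3, value 1
    geo <- smallGeometry()           # 33 x 33 at 2 mm, step 0.5
    drr <- renderDRR(vol, Pose(), geo, normalize = FALSE)
    acc <- pixelValues(drr)

    probe <- rbind(c(17, 17), c(1, 1), c(5, 20), c(9, 9), c(17, 3),
                   c(25, 25), c(30, 10), c(2, 31), c(13, 28), c(22, 6))
    for (k in seq_len(nrow(probe))) {
        r <- probe[k, 1]; c <- probe[k, 2]
        pix <- geo@detectorCenter +
            geo@detectorU * (c - 1 - 16) * geo@pixelSpacing +
            geo@detectorV * (r - 1 - 16) * geo@pixelSpacing
        u <- (pix - geo@source) / sqrt(sum((pix - geo@source)^2))
        chord <- rayBoxChord(geo@source, u, rep(-32, 3), rep(32, 3))
        expect_lt(abs(acc[r, c] - chord), 2 * geo@stepSize)
    }
})

test_that("accumulation is linear in the voxel intensities", {
    set.seed(3)
    vox <- array(runif(20^3), rep(20, 3))
    vol <- CTVolume(vox)
    geo <- smallGeometry(n = 17L, pixelSpacing = 2)
    a1 <- pixelValues(renderDRR(vol, Pose(thetaY = 20), geo, normalize = FALSE))
    a2 <- pixelValues(renderDRR(CTVolume(2 * vox), Pose(thetaY = 20), geo,
                                normalize = FALSE))
    expect_identical(a2, 2 * a1)

    zero <- renderDRR(CTVolume(array(0, rep(16, 3))), Pose(), geo,
                      normalize = FALSE)
    expect_true(all(pixelValues(zero) == 0))
})

test_that("rendering is covariant under consistent origin shifts", {
    set.seed(9)
    vox <- array(runif(24^3), rep(24, 3))
    vol <- CTVolume(vox)
    geo <- smallGeometry(n = 21L)
    base <- pixelValues(renderDRR(vol, Pose(), geo, normalize = FALSE))

    shift <- c(5, -3, 2)
    vol2 <- CTVolume(vox, origin = volumeOrigin(vol) + shift)
    geo2 <- ProjectionGeometry(geo@source + shift,
                               geo@detectorCenter + shift,
                               geo@detectorU, geo@detectorV,
                               geo@detectorSize, geo@pixelSpacing,
                               geo@stepSize)
    moved <- pixelValues(renderDRR(vol2, Pose(), geo2, normalize = FALSE))
    expect_equal(moved, base, tolerance = 1e-6)
})

test_that("geometry that misses the volume warns and returns zeros", {
    vol <- CTVolume(array(1, rep(16, 3)), origin = c(5000, 5000, 5000))
    geo <- smallGeometry(n = 9L)
    expect_warning(drr <- renderDRR(vol, Pose(), geo, normalize = FALSE),
                   "no ray")
    expect_true(all(pixelValues(drr) == 0))
})

test_that("grayscale conversion maps accumulations onto [0, 255]", {
    vol <- unitCubeVolume(33L)
    geo <- smallGeometry(n = 33L)  # field of view wider than the cube
    g <- pixelValues(renderDRR(vol, Pose(), geo, normalize = TRUE))
    expect_equal(range(g), c(0, 255))
    expect_true(all(toGrayscale(matrix(7, 4, 4)) == 0))
})

test_that("batch rendering is order-preserving and equals single renders", {
    vol <- CTVolume(array(runif(18^3), rep(18, 3)))
    geo <- smallGeometry(n = 13L)

    same <- renderBatch(vol, rep(list(Pose(tX = 2)), 3), geo,
                        normalize = FALSE)
    expect_identical(pixelValues(same[[1]]), pixelValues(same[[2]]))
    expect_identical(pixelValues(same[[1]]), pixelValues(same[[3]]))

    poses <- lapply(41:45, randomPose)
    batch <- renderBatch(vol, poses, geo, normalize = FALSE)
    for (k in seq_along(poses))
        expect_identical(pixelValues(batch[[k]]),
                         pixelValues(renderDRR(vol, poses[[k]], geo,
                                               normalize = FALSE)))

    expect_identical(renderBatch(vol, list(), geo), list())
    expect_error(renderBatch(vol, list(Pose(), "not a pose"), geo),
                 "index 2")
})
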