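## Small shared fixtures, built in code.

## deterministic random pose within modest bounds
randomPose <- function(seed) {
    set.seed(seed)
    poseFromVector(c(runif(3, -20, 20), runif(3, -40, 40)))
}

## homogeneous unit cube: 65^3 voxels at 1 mm, support [-32, 32]^3
unitCubeVolume <- function(side = 65L, value = 1)
    CTVolume(array(value, rep(side, 3)), spacing = c(1, 1, 1))

## small, fast frontal geometry
smallGeometry <- function(n = 33L, pixelSpacing = 2, stepSize = 0.5)
    makeDefaultGeometry("frontal", detectorSize = c(n, n),
                        pixelSpacing = pixelSpacing, stepSize = stepSize)

## compact phantom + geometry for fast end-to-end tests
quickPhantomSpec <- function(seed = 1, noiseSd = 0) {
    PhantomSpec(dim = c(48L, 48L, 48L), spacing = c(2, 2, 2),
                background = 100, noiseSd = noiseSd, seed = seed,
                primitives = list(
                    list(type = "cylinder", center = c(0, -22, 0), axis = "y",
                         radius = 12, halfLength = 9, intensity = 300),
                    list(type = "cylinder", center = c(0, 0, 0), axis = "y",
                         radius = 12, halfLength = 9, intensity = 300),
                    list(type = "cylinder", center = c(0, 22, 0), axis = "y",
                         radius = 12, halfLength = 9, intensity = 300),
                    list(type = "box", center = c(0, 0, 17),
                         halfWidths = c(3, 30, 5), intensity = 300)))
}

quickGeometry <- function()
    makeDefaultGeometry("frontal", detectorSize = c(64L, 64L),
                        pixelSpacing = 4, stepSize = 2)

## contour set helper from explicit (row, col) pairs
pointSet <- function(pts, dim) ContourPointSet(pts, dim)
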