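test_that("contour extraction finds object boundaries", {
    ## constant images carry no contours
    expect_equal(numPoints(extractContours(matrix(0, 32, 32))), 0)
    expect_equal(numPoints(extractContours(matrix(200, 32, 32))), 0)
    expect_error(extractContours(matrix(0, 2, 2)), "3 x 3")

    ## filled bright square: points on (or adjacent to) the boundary ring,
    ## count close to the enumerated perimeter
    img <- matrix(0, 64, 64)
    img[20:39, 20:39] <- 255
    cp <- contourPoints(extractContours(img))
    ring <- (pmax(abs(cp[, 1] - 29.5), abs(cp[, 2] - 29.5)))
    expect_true(all(ring >= 8.5 & ring <= 11.5))  # within 1 px of the edge
    perimeter <- 4 * 20 - 4                        # direct enumeration: 76
    expect_gte(nrow(cp), perimeter - 8)
    expect_lte(nrow(cp), perimeter + 8)

    ## vertical step edge localizes on one of the two step columns
    step <- cbind(matrix(0, 64, 32), matrix(255, 64, 32))
    sp <- contourPoints(extractContours(step))
    expect_true(all(sp[, 2] %in% c(32, 33)))
    expect_gte(nrow(sp), 55)

    ## points arrive in row-major scan order
    expect_false(is.unsorted(sp[, 1]))
})

test_that("match scores follow the banded rule", {
    b <- SimilarityBands()           # a = 1, b = 3, w1 = 0.8, w2 = 0.5
    expect_equal(matchScore(0, b), 1)
    expect_equal(matchScore(1, b), 0.8)      # boundary of the inner band
    expect_equal(matchScore(2, b), 0.5)
    expect_equal(matchScore(3, b), 0.5)      # boundary of the outer band
    expect_equal(matchScore(3.1, b), 0)
    expect_error(matchScore(-1, b), "non-negative")
    ## non-increasing in d
    d <- seq(0, 5, by = 0.25)
    expect_true(all(diff(matchScore(d, b)) <= 0))
})

test_that("contour similarity matches enumeration on constructed cases", {
    dims <- c(100L, 100L)
    ref <- pointSet(cbind(5, seq(5, 95, by = 10)), dims)

    ## identical sets score exactly 1
    expect_identical(contourSimilarity(ref, ref), 1)

    ## 5 coincident + 5 one-pixel displaced -> (5 * 1 + 5 * 0.8) / 10
    flo <- contourPoints(ref)
    flo[6:10, 2] <- flo[6:10, 2] + 1L
    expect_equal(contourSimilarity(ref, pointSet(flo, dims)), 0.9)

    ## isolated line translated beyond the outer band scores 0
    line <- pointSet(cbind(10:40, 20), c(60L, 60L))
    shifted <- pointSet(cbind(10:40, 24), c(60L, 60L))
    expect_equal(contourSimilarity(line, shifted), 0)

    ## perpendicular shifts: non-increasing, zero past the outer band
    sims <- vapply(0:5, function(k)
        contourSimilarity(line, pointSet(cbind(10:40, 20 + k), c(60L, 60L))),
        numeric(1))
    expect_true(all(diff(sims) <= 0))
    expect_equal(sims[1], 1)
    expect_true(all(sims[5:6] == 0))
})

test_that("window search agrees with the all-pairs oracle", {
    set.seed(11)
    dims <- c(40L, 40L)
    for (rep in 1:20) {
        nr <- sample(3:25, 1); nf <- sample(0:25, 1)
        rpts <- unique(cbind(sample(40, nr, TRUE), sample(40, nr, TRUE)))
        fpts <- unique(cbind(sample(40, nf, TRUE), sample(40, nf, TRUE)))
        got <- contourSimilarity(pointSet(rpts, dims),
                                 pointSet(fpts, dims))
        want <- naiveContourSimilarity(rpts, fpts)
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("the similarity is asymmetric and guards empty references", {
    dims <- c(30L, 30L)
    one <- pointSet(cbind(5, 5), dims)
    two <- pointSet(rbind(c(5, 5), c(20, 20)), dims)
    expect_equal(contourSimilarity(one, two), 1)
    expect_equal(contourSimilarity(two, one), 0.5)

    empty <- pointSet(matrix(integer(0), 0, 2), dims)
    expect_error(contourSimilarity(empty, one), "empty")
    ## an empty floating set is allowed and scores 0
    expect_equal(contourSimilarity(one, empty), 0)
    ## shape mismatch is an error
    expect_error(contourSimilarity(one, pointSet(cbind(5, 5), c(31L, 30L))),
                 "same shape")
})

test_that("composite similarity is the exact weighted sum", {
    w <- CompositeWeights(0.6, 0.4)
    expect_equal(compositeSimilarity(1, 1, w), 1)
    expect_equal(compositeSimilarity(0.8, 0.5, w), 0.68)
    ## degenerate lateral evidence reduces to the weighted frontal score
    expect_equal(compositeSimilarity(0.7, 0, w), 0.6 * 0.7)
    ## linear in each argument, bounded by wf + wl
    expect_equal(compositeSimilarity(0.5, 0.25, w),
                 (compositeSimilarity(1, 0.5, w)) / 2)
    expect_lte(compositeSimilarity(1, 1, CompositeWeights(0.55, 0.35)), 0.9)

    expect_error(CompositeWeights(0.4, 0.6), "wf > wl")
    expect_error(CompositeWeights(0.5, 0.5), "wf > wl")
    expect_error(CompositeWeights(0.7, 0.4), "<= 1")
    expect_error(compositeSimilarity(1.2, 0, w), "\\[0, 1\\]")
})

test_that("band parameters are validated", {
    expect_error(SimilarityBands(aBand = 3, bBand = 1), "aBand < bBand")
    expect_error(SimilarityBands(w1 = 0.4, w2 = 0.5), "w1 > w2")
    expect_error(SimilarityBands(w1 = 1.2), "w1")
})
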