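sphere <- function(x) sum(x^2)

test_that("optimizer configuration is validated", {
    expect_error(DEConfig(NP = 5, D = 2, lower = 0, upper = 1), "NP")
    expect_error(DEConfig(D = 2, lower = 1, upper = 0), "lower < upper")
    expect_error(DEConfig(D = 2, lower = 0, upper = 1, crFirst = 0.4),
                 "crFirst > 0.5 > crSecond")
    expect_error(DEConfig(D = 2, lower = 0, upper = 1, crSecond = 0.6),
                 "crFirst > 0.5 > crSecond")
    expect_error(DEConfig(D = 2, lower = 0, upper = 1, fFirst = 0), "F values")
    expect_error(DEConfig(D = 2, lower = 0, upper = 1, fSecond = 2.5),
                 "F values")
})

test_that("population initialization is seeded, bounded and injectable", {
    cfg <- DEConfig(NP = 10, D = 6, Gmax = 10, lower = 0, upper = 1, seed = 5)
    p1 <- initializePopulation(cfg, sphere)
    p2 <- initializePopulation(cfg, sphere)
    expect_identical(p1@vectors, p2@vectors)
    expect_identical(p1@fitness, p2@fitness)
    expect_equal(dim(p1@vectors), c(10, 6))
    expect_true(all(p1@vectors >= 0 & p1@vectors < 1))
    expect_equal(p1@bestIndex, which.min(p1@fitness))

    inj <- DEConfig(NP = 10, D = 6, Gmax = 10, lower = 0, upper = 1, seed = 5,
                    initial = matrix(0.5, 1, 6))
    pi <- initializePopulation(inj, sphere)
    expect_equal(pi@vectors[1, ], rep(0.5, 6))
    ## remaining rows keep the seeded draw
    expect_identical(pi@vectors[-1, ], p1@vectors[-1, ])
})

test_that("control parameters switch at the halfway generation", {
    cfg <- DEConfig(NP = 10, D = 6, Gmax = 50, lower = 0, upper = 1,
                    fScale = c(1, 1, 0.8, 1, 1, 1))
    early <- phaseControls(1, 50, cfg)
    late <- phaseControls(26, 50, cfg)
    expect_equal(early$F[1], 0.5)
    expect_equal(late$F[1], 0.8)
    expect_equal(early$CR, 0.9)
    expect_equal(late$CR, 0.3)
    ## damped depth dimension: 0.8 * 0.8 in the second stage
    expect_equal(late$F[3], 0.64)
    ## odd Gmax: the first stage includes the ceiling generation
    expect_equal(phaseControls(3, 5, cfg)$F[1], 0.5)
    expect_equal(phaseControls(4, 5, cfg)$F[1], 0.8)
    expect_error(phaseControls(0, 50, cfg))
})

test_that("DE/rand/2 mutation combines five donors and clips to bounds", {
    X <- rbind(c(1, 2), c(0.5, 0), c(0, 0.5), c(1, 1), c(1, 0), c(0, 0))
    v <- deMutate(X, 6, fVec = 0.5, lower = rep(-10, 2), upper = rep(10, 2),
                  donors = 1:5)
    expect_equal(v, c(1.25, 2.25))  # hand arithmetic

    ## zero scale factor returns the base donor
    expect_equal(deMutate(X, 6, fVec = 0, lower = rep(-10, 2),
                          upper = rep(10, 2), donors = 1:5), X[1, ])

    ## identical population collapses to that vector
    same <- matrix(3, 8, 2)
    set.seed(1)
    expect_equal(deMutate(same, 1, fVec = 0.7, lower = rep(-10, 2),
                          upper = rep(10, 2)), c(3, 3))

    ## clipping keeps the mutant inside the box
    v2 <- deMutate(X * 100, 6, fVec = 1, lower = rep(-5, 2), upper = rep(5, 2),
                   donors = 1:5)
    expect_true(all(v2 >= -5 & v2 <= 5))

    expect_error(deMutate(X[1:5, ], 1, 0.5, rep(0, 2), rep(1, 2)), "NP >= 6")
})

test_that("donor indices are mutually distinct and exclude the target", {
    set.seed(99)
    for (k in 1:10000) {
        idx <- DualPoseReg:::.drawDistinctIndices(8, 5, 3)
        expect_length(unique(idx), 5)
        expect_false(3 %in% idx)
    }
})

test_that("binomial crossover forces one mutant coordinate", {
    target <- c(0, 0, 0, 0)
    mutant <- c(1, 2, 3, 4)
    set.seed(21)
    u0 <- deCrossover(target, mutant, cr = 0)
    expect_equal(sum(u0 != target), 1)   # only j_rand survives

    u1 <- deCrossover(target, mutant, cr = 1)
    expect_equal(u1, mutant)

    ## step replay: identical draws reproduce the trial exactly
    set.seed(77)
    jr <- floor(runif(1) * 4) + 1
    take <- runif(4) < 0.5
    take[jr] <- TRUE
    want <- ifelse(take, mutant, target)
    set.seed(77)
    expect_identical(deCrossover(target, mutant, cr = 0.5), want)
})

test_that("selection is greedy with ties keeping the incumbent", {
    f <- function(x) x[1]
    s1 <- deSelect(c(2), c(1), f)
    expect_true(s1$replaced); expect_equal(s1$fitness, 1)
    s2 <- deSelect(c(2), c(2), f)
    expect_false(s2$replaced)
    s3 <- deSelect(c(2), c(3), f)
    expect_false(s3$replaced); expect_equal(s3$vector, c(2))
    expect_error(deSelect(c(1), c(NaN), function(x) x[1]), "non-finite")
})

test_that("the optimizer converges, is elitist, bounded and reproducible", {
    cfg <- DEConfig(NP = 10, D = 1, Gmax = 100, lower = -5, upper = 5,
                    seed = 3)
    res <- optimizePDE(function(x) (x - 2)^2, cfg)
    expect_lt(abs(bestVector(res) - 2), 1e-3)
    expect_equal(evaluationCount(res), 10 * 101)
    expect_true(all(diff(fitnessTrace(res)) <= 0))

    ## constant objective: flat trace at the constant
    resC <- optimizePDE(function(x) 42, cfg)
    expect_true(all(fitnessTrace(resC) == 42))
    expect_equal(bestFitness(resC), 42)

    ## identical seed + config give identical results
    cfg2 <- DEConfig(NP = 8, D = 3, Gmax = 30, lower = -2, upper = 2,
                     seed = 11)
    r1 <- optimizePDE(sphere, cfg2)
    r2 <- optimizePDE(sphere, cfg2)
    expect_identical(bestVector(r1), bestVector(r2))
    expect_identical(fitnessTrace(r1), fitnessTrace(r2))

    ## objective errors carry generation/individual context
    flaky <- function(x) if (sum(x) > 1e9) 0 else stop("boom")
    expect_error(optimizePDE(flaky, cfg2), "generation")
})

test_that("bounds hold at every generation", {
    cfg <- DEConfig(NP = 6, D = 2, Gmax = 40, lower = c(-1, 0),
                    upper = c(1, 2), seed = 13)
    seen <- NULL
    res <- optimizePDE(function(x) {
        seen <<- rbind(seen, x)
        sphere(x)
    }, cfg)
    expect_true(all(seen[, 1] >= -1 & seen[, 1] <= 1))
    expect_true(all(seen[, 2] >= 0 & seen[, 2] <= 2))
})

test_that("a straight-line replay reproduces the optimizer step for step", {
    cfg <- DEConfig(NP = 6, D = 2, Gmax = 3, lower = -4, upper = 4, seed = 17)
    res <- optimizePDE(sphere, cfg)
    want <- replayPDE(sphere, NP = 6, D = 2, Gmax = 3, lower = -4, upper = 4,
                      seed = 17)
    expect_identical(fitnessTrace(res), want$trace)
    expect_identical(bestFitness(res), min(want$fitness))
    expect_identical(bestVector(res),
                     want$vectors[which.min(want$fitness), ])

    ## and over a longer horizon with the phase switch in play
    cfgL <- DEConfig(NP = 7, D = 3, Gmax = 20, lower = -3, upper = 3,
                     seed = 23)
    resL <- optimizePDE(sphere, cfgL)
    wantL <- replayPDE(sphere, NP = 7, D = 3, Gmax = 20, lower = -3,
                       upper = 3, seed = 23)
    expect_identical(fitnessTrace(resL), wantL$trace)
})
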