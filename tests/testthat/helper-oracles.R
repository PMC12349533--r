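## Independent oracles: brute-force reimplementations kept deliberately
## separate from the package's code paths.

## element-by-element 4x4 matrix product
naiveMatMul4 <- function(a, b) {
    out <- matrix(0, 4, 4)
    for (i in 1:4)
        for (j in 1:4)
            for (k in 1:4)
                out[i, j] <- out[i, j] + a[i, k] * b[k, j]
    out
}

## nested-loop 8-corner trilinear weighting at a world point
trilinearOracle <- function(vox, spacing, origin, p) {
    idx <- (p - origin) / spacing
    d <- dim(vox)
    if (any(idx < 0) || any(idx > d - 1)) return(0)
    i0 <- pmin(floor(idx), d - 2)
    f <- idx - i0
    acc <- 0
    for (dx in 0:1)
        for (dy in 0:1)
            for (dz in 0:1) {
                w <- (if (dx) f[1] else 1 - f[1]) *
                     (if (dy) f[2] else 1 - f[2]) *
                     (if (dz) f[3] else 1 - f[3])
                acc <- acc + w * vox[i0[1] + dx + 1, i0[2] + dy + 1,
                                     i0[3] + dz + 1]
            }
    acc
}

## slab-method chord length of a ray (origin o, unit direction u) through an
## axis-aligned box [lo, hi]; 0 when the ray misses
rayBoxChord <- function(o, u, lo, hi) {
    t0 <- -Inf; t1 <- Inf
    for (k in 1:3) {
        if (abs(u[k]) < 1e-12) {
            if (o[k] < lo[k] || o[k] > hi[k]) return(0)
        } else {
            ta <- (lo[k] - o[k]) / u[k]
            tb <- (hi[k] - o[k]) / u[k]
            t0 <- max(t0, min(ta, tb))
            t1 <- min(t1, max(ta, tb))
        }
    }
    t0 <- max(t0, 0)
    if (t1 <= t0) return(0)
    t1 - t0
}

## all-pairs nearest-distance banded similarity (no window search)
naiveContourSimilarity <- function(refPts, floPts, aBand = 1, bBand = 3,
                                   w1 = 0.8, w2 = 0.5) {
    total <- 0
    for (i in seq_len(nrow(refPts))) {
        if (nrow(floPts) == 0) next
        d <- sqrt((floPts[, 1] - refPts[i, 1])^2 +
                  (floPts[, 2] - refPts[i, 2])^2)
        dm <- min(d)
        total <- total + if (dm == 0) 1
            else if (dm <= aBand) w1
            else if (dm <= bBand) w2
            else 0
    }
    total / nrow(refPts)
}

## straight-line phased-DE replay following the documented draw order:
## init NP*D uniforms column-major; per individual 5 rejection-sampled donor
## indices, j_rand, then D crossover uniforms; in-place greedy selection
replayPDE <- function(objective, NP, D, Gmax, lower, upper,
                      fFirst = 0.5, fSecond = 0.8, crFirst = 0.9,
                      crSecond = 0.3, fScale = rep(1, D), seed = 1) {
    lower <- rep_len(lower, D); upper <- rep_len(upper, D)
    set.seed(seed)
    X <- matrix(lower, NP, D, byrow = TRUE) +
        matrix(runif(NP * D), NP, D) *
        matrix(upper - lower, NP, D, byrow = TRUE)
    fit <- numeric(NP)
    for (i in 1:NP) fit[i] <- objective(X[i, ])
    trace <- numeric(Gmax)
    for (G in 1:Gmax) {
        first <- G <= ceiling(Gmax / 2)
        Fv <- (if (first) fFirst else fSecond) * fScale
        CR <- if (first) crFirst else crSecond
        for (i in 1:NP) {
            idx <- integer(0)
            while (length(idx) < 5) {
                cand <- floor(runif(1) * NP) + 1
                if (cand != i && !(cand %in% idx)) idx <- c(idx, cand)
            }
            v <- X[idx[1], ] + Fv * (X[idx[2], ] - X[idx[3], ]) +
                Fv * (X[idx[4], ] - X[idx[5], ])
            v <- pmin(pmax(v, lower), upper)
            jr <- floor(runif(1) * D) + 1
            take <- runif(D) < CR
            take[jr] <- TRUE
            u <- ifelse(take, v, X[i, ])
            fu <- objective(u)
            if (fu < fit[i]) {
                X[i, ] <- u
                fit[i] <- fu
            }
        }
        trace[G] <- min(fit)
    }
    list(vectors = X, fitness = fit, trace = trace)
}
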