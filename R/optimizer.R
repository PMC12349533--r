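## Phased differential evolution: DE/rand/2 mutation, binomial crossover,
## greedy selection, stage-switched F and CR with per-dimension F scaling.
##
## RNG draw order (fixed so that step-replay oracles are well defined):
##   initialization  NP * D uniforms, filling the NP x D matrix column-major;
##   per individual  (1) donor indices r1..r5 by rejection sampling, each
##                       candidate floor(runif(1) * NP) + 1,
##                   (2) j_rand = floor(runif(1) * D) + 1,
##                   (3) D crossover uniforms.

#' Initialize a DE population
#'
#' Seeds the RNG from `config@seed` and draws `NP` vectors uniformly within
#' the bounds (column-major fill of the NP x D matrix). Rows of
#' `config@initial`, if any, replace the first rows after drawing, so the
#' draw count is independent of injections. All vectors are evaluated.
#'
#' @param config a [DEConfig-class].
#' @param objective function mapping a numeric(D) vector to a finite scalar.
#' @return A [Population-class] at generation 0.
#' @export
initializePopulation <- function(config, objective) {
    stopifnot(is(config, "DEConfig"), is.function(objective))
    set.seed(config@seed)
    NP <- config@NP; D <- config@D
    vecs <- matrix(config@lower, NP, D, byrow = TRUE) +
        matrix(runif(NP * D), NP, D) *
        matrix(config@upper - config@lower, NP, D, byrow = TRUE)
    if (nrow(config@initial))
        vecs[seq_len(nrow(config@initial)), ] <- config@initial
    fit <- apply(vecs, 1, function(x) .evalObjective(objective, x))
    new("Population", vectors = vecs, fitness = fit, generation = 0L,
        bestIndex = which.min(fit))
}

.evalObjective <- function(objective, x) {
    f <- objective(x)
    if (!is.numeric(f) || length(f) != 1 || !is.finite(f))
        stop("objective returned a non-finite value at (",
             paste(format(x), collapse = ", "), ")", call. = FALSE)
    f
}

#' Stage-switched control parameters
#'
#' The evolution is split in two stages at the halfway generation: the base
#' scale factor is `fFirst` while `G <= ceiling(Gmax / 2)` and `fSecond`
#' afterwards (0.5 then 0.8 by default), and the crossover rate switches from
#' `crFirst` (> 0.5) to `crSecond` (< 0.5). The returned F vector is the base
#' F times the per-dimension `fScale` (used to damp the depth dimension in
#' registration).
#'
#' @param G generation index, 1-based.
#' @param Gmax total generations.
#' @param config a [DEConfig-class].
#' @return `list(F = numeric(D), CR = numeric(1))`.
#' @examples
#' cfg <- DEConfig(D = 2, lower = 0, upper = 1, Gmax = 50)
#' phaseControls(1, 50, cfg)$CR   # first stage
#' phaseControls(26, 50, cfg)$CR  # second stage
#' @export
phaseControls <- function(G, Gmax, config) {
    stopifnot(is(config, "DEConfig"), G >= 1, G <= Gmax)
    first <- G <= ceiling(Gmax / 2)
    baseF <- if (first) config@fFirst else config@fSecond
    cr <- if (first) config@crFirst else config@crSecond
    list(F = baseF * config@fScale, CR = cr)
}

## rejection-sample k mutually distinct indices in 1..n, all different from
## `exclude`; consumes one uniform per accepted or rejected candidate
.drawDistinctIndices <- function(n, k, exclude) {
    picked <- integer(0)
    while (length(picked) < k) {
        cand <- floor(runif(1) * n) + 1
        if (cand != exclude && !(cand %in% picked))
            picked <- c(picked, cand)
    }
    picked
}

#' DE/rand/2 mutation
#'
#' Draws five mutually distinct donor indices (all different from the target
#' `i`) and forms `V = X[r1] + F * (X[r2] - X[r3]) + F * (X[r4] - X[r5])`,
#' clipped to the bounds. `F` may be a per-dimension vector.
#'
#' @param vectors NP x D population matrix.
#' @param i target index (excluded from the donors).
#' @param fVec numeric F, scalar or length D.
#' @param lower,upper box bounds.
#' @param donors optional integer(5) donor indices, bypassing the random draw
#'   (used for worked examples and tests).
#' @return The mutant numeric(D) vector.
#' @export
deMutate <- function(vectors, i, fVec, lower, upper, donors = NULL) {
    NP <- nrow(vectors)
    if (NP < 6) stop("DE/rand/2 requires NP >= 6")
    stopifnot(i >= 1, i <= NP)
    if (is.null(donors)) donors <- .drawDistinctIndices(NP, 5, i)
    stopifnot(length(donors) == 5)
    v <- vectors[donors[1], ] +
        fVec * (vectors[donors[2], ] - vectors[donors[3], ]) +
        fVec * (vectors[donors[4], ] - vectors[donors[5], ])
    .clamp(v, lower, upper)
}

#' Binomial crossover
#'
#' Takes the mutant coordinate where `runif(1) < CR` or at the forced
#' coordinate `j_rand` (drawn uniformly once per trial), otherwise the target
#' coordinate; at least one mutant coordinate always survives.
#'
#' @param target,mutant numeric(D) vectors.
#' @param cr crossover rate.
#' @return The trial numeric(D) vector.
#' @export
deCrossover <- function(target, mutant, cr) {
    stopifnot(length(target) == length(mutant))
    D <- length(target)
    jrand <- floor(runif(1) * D) + 1
    take <- runif(D) < cr
    take[jrand] <- TRUE
    ifelse(take, mutant, target)
}

#' Greedy one-to-one selection
#'
#' The trial replaces the target iff its objective value is strictly lower;
#' ties keep the incumbent.
#'
#' @param target numeric(D) incumbent vector.
#' @param trial numeric(D) trial vector.
#' @param objective the objective function.
#' @param targetFitness cached objective value of `target`; evaluated when
#'   missing.
#' @return `list(vector, fitness, replaced)`.
#' @export
deSelect <- function(target, trial, objective,
                     targetFitness = .evalObjective(objective, target)) {
    ft <- .evalObjective(objective, trial)
    if (ft < targetFitness)
        list(vector = trial, fitness = ft, replaced = TRUE)
    else
        list(vector = target, fitness = targetFitness, replaced = FALSE)
}

#' Run the phased differential-evolution optimizer
#'
#' Minimizes `objective` over the box in `config`: initialization, then per
#' generation the stage controls, DE/rand/2 mutation, binomial crossover and
#' greedy selection (population updated in place within the generation).
#' Exactly `NP * (Gmax + 1)` objective evaluations are performed. To maximize
#' a similarity, pass its negation.
#'
#' @param objective function mapping numeric(D) to a finite scalar.
#' @param config a [DEConfig-class].
#' @return An [OptimizationResult-class] whose trace (best-so-far per
#'   generation) is non-increasing.
#' @examples
#' cfg <- DEConfig(NP = 10, D = 1, Gmax = 100, lower = -5, upper = 5, seed = 7)
#' res <- optimizePDE(function(x) (x - 2)^2, cfg)
#' bestVector(res)
#' @export
optimizePDE <- function(objective, config) {
    stopifnot(is(config, "DEConfig"))
    pop <- tryCatch(initializePopulation(config, objective),
        error = function(e) stop("objective failed at generation 0 ",
                                 "(initialization): ", conditionMessage(e),
                                 call. = FALSE))
    vecs <- pop@vectors
    fit <- pop@fitness
    NP <- config@NP
    Gmax <- config@Gmax
    evals <- NP
    trace <- numeric(Gmax)
    for (G in seq_len(Gmax)) {
        ctl <- phaseControls(G, Gmax, config)
        for (i in seq_len(NP)) {
            v <- deMutate(vecs, i, ctl$F, config@lower, config@upper)
            u <- deCrossover(vecs[i, ], v, ctl$CR)
            sel <- tryCatch(
                deSelect(vecs[i, ], u, objective, targetFitness = fit[i]),
                error = function(e) stop("objective failed at generation ", G,
                                         ", individual ", i, ": ",
                                         conditionMessage(e), call. = FALSE))
            evals <- evals + 1L
            vecs[i, ] <- sel$vector
            fit[i] <- sel$fitness
        }
        trace[G] <- min(fit)
    }
    b <- which.min(fit)
    new("OptimizationResult", bestVector = vecs[b, ], bestFitness = fit[b],
        trace = trace, evaluations = as.integer(evals), seed = config@seed)
}

#' Write an optimization trace as CSV
#'
#' @param result an [OptimizationResult-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(result, path) {
    stopifnot(is(result, "OptimizationResult"))
    write.csv(data.frame(generation = seq_along(result@trace),
                         best = result@trace),
              path, row.names = FALSE)
    invisible(path)
}
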