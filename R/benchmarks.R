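## The six benchmark functions used to characterize the optimizer, with their
## printed search boxes and theoretical optima, plus the convergence-protocol
## runner (1000 iterations, population 30 by default).

## penalty term of the generalized penalized functions
.uPenalty <- function(x, a, k, m) {
    p <- numeric(length(x))
    hi <- x > a
    lo <- x < -a
    p[hi] <- k * (x[hi] - a)^m
    p[lo] <- k * (-x[lo] - a)^m
    p
}

.f1Schwefel222 <- function(x) sum(abs(x)) + prod(abs(x))

.f2Schwefel12 <- function(x) sum(cumsum(x)^2)

.f3Schwefel221 <- function(x) max(abs(x))

.f4Penalized1 <- function(x) {
    D <- length(x)
    y <- 1 + (x + 1) / 4
    (pi / D) * (10 * sin(pi * y[1])^2 +
        sum((y[-D] - 1)^2 * (1 + 10 * sin(pi * y[-1])^2)) +
        (y[D] - 1)^2) + sum(.uPenalty(x, 10, 100, 4))
}

.f5Penalized2 <- function(x) {
    D <- length(x)
    0.1 * (sin(3 * pi * x[1])^2 +
        sum((x[-D] - 1)^2 * (1 + sin(3 * pi * x[-1])^2)) +
        (x[D] - 1)^2 * (1 + sin(2 * pi * x[D])^2)) +
        sum(.uPenalty(x, 5, 100, 4))
}

## Kowalik 11-term least squares; canonical data table
.kowalikA <- c(0.1957, 0.1947, 0.1735, 0.1600, 0.0844, 0.0627,
               0.0456, 0.0342, 0.0323, 0.0235, 0.0246)
.kowalikB <- 1 / c(0.25, 0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16)

.f6Kowalik <- function(x) {
    b <- .kowalikB
    sum((.kowalikA - x[1] * (b^2 + b * x[2]) / (b^2 + b * x[3] + x[4]))^2)
}

## registry; literature global minimizers (F6's quoted to 6 decimals)
.benchmarkRegistry <- list(
    F1 = list(longName = "Schwefel 2.22", D = 30L, lower = -10, upper = 10,
              optimum = 0, minimizer = rep(0, 30), fun = .f1Schwefel222),
    F2 = list(longName = "Schwefel 1.2", D = 30L, lower = -100, upper = 100,
              optimum = 0, minimizer = rep(0, 30), fun = .f2Schwefel12),
    F3 = list(longName = "Schwefel 2.21", D = 30L, lower = -100, upper = 100,
              optimum = 0, minimizer = rep(0, 30), fun = .f3Schwefel221),
    F4 = list(longName = "Generalized Penalized 1", D = 30L, lower = -50,
              upper = 50, optimum = 0, minimizer = rep(-1, 30),
              fun = .f4Penalized1),
    F5 = list(longName = "Generalized Penalized 2", D = 30L, lower = -50,
              upper = 50, optimum = 0, minimizer = rep(1, 30),
              fun = .f5Penalized2),
    F6 = list(longName = "Kowalik", D = 4L, lower = -5, upper = 5,
              optimum = 0.0003075,
              minimizer = c(0.192833, 0.190836, 0.123117, 0.135766),
              fun = .f6Kowalik))

#' List the registered benchmark functions
#'
#' @return Character vector of benchmark ids ("F1".."F6").
#' @export
listBenchmarks <- function() names(.benchmarkRegistry)

#' Retrieve a benchmark function definition
#'
#' F1 Schwefel 2.22 (sum plus product of absolute coordinates), F2 Schwefel
#' 1.2 (sum of squared prefix sums), F3 Schwefel 2.21 (maximum absolute
#' coordinate), F4/F5 Generalized Penalized 1/2 (sinusoidal sums with the
#' u(x, a, k, m) boundary penalty), F6 Kowalik (11-term least squares).
#' D = 30 for F1-F5 and 4 for F6 (its canonical arity).
#'
#' @param name benchmark id, one of `listBenchmarks()`.
#' @return A [BenchmarkFunction-class].
#' @examples
#' benchmarkFunction("F6")
#' @export
benchmarkFunction <- function(name) {
    if (!name %in% names(.benchmarkRegistry))
        stop("unknown benchmark function '", name, "'")
    e <- .benchmarkRegistry[[name]]
    new("BenchmarkFunction", name = name, longName = e$longName, D = e$D,
        lower = e$lower, upper = e$upper, optimum = e$optimum,
        minimizer = e$minimizer, fun = e$fun)
}

#' Evaluate a benchmark function
#'
#' @param name benchmark id.
#' @param x numeric vector of the function's dimensionality, inside its box.
#' @return The function value.
#' @examples
#' evaluateBenchmark("F3", c(3, -7, 2, rep(0, 27)))  # 7
#' @export
evaluateBenchmark <- function(name, x) {
    bf <- benchmarkFunction(name)
    if (length(x) != bf@D)
        stop(name, " expects dimension ", bf@D, ", got ", length(x))
    if (any(x < bf@lower - 1e-12) || any(x > bf@upper + 1e-12))
        stop("x lies outside the search box of ", name)
    bf@fun(as.numeric(x))
}

#' Run the benchmark convergence protocol
#'
#' Runs an optimizer on each named benchmark function for each seed and
#' collects per-generation best-so-far traces. Defaults follow the protocol
#' used to characterize the phased-DE optimizer: 1000 iterations and
#' population 30. Alternative optimizers can be plugged in through
#' `optimizer`, any function with the `optimizePDE(objective, config)`
#' contract.
#'
#' @param functions character vector of benchmark ids.
#' @param iterations generations per run.
#' @param population population size.
#' @param seeds integer vector; one run per (function, seed).
#' @param optimizer optimizer function; default [optimizePDE()].
#' @param optimizerName label stored in the records.
#' @param ... further arguments passed to [DEConfig()] (e.g. `crFirst`).
#' @return List of [ConvergenceRecord-class], functions varying slowest.
#' @export
runConvergenceExperiment <- function(functions = listBenchmarks(),
                                     iterations = 1000, population = 30,
                                     seeds = 1:10, optimizer = optimizePDE,
                                     optimizerName = "PDE", ...) {
    records <- list()
    for (fn in functions) {
        bf <- benchmarkFunction(fn)
        for (s in seeds) {
            cfg <- DEConfig(NP = population, D = bf@D, Gmax = iterations,
                            lower = bf@lower, upper = bf@upper,
                            seed = s, ...)
            res <- optimizer(bf@fun, cfg)
            records[[length(records) + 1]] <-
                new("ConvergenceRecord", functionName = fn,
                    optimizerName = optimizerName,
                    trace = fitnessTrace(res), best = bestFitness(res),
                    seed = as.integer(s))
        }
    }
    records
}

#' Summarize convergence records
#'
#' @param records list of [ConvergenceRecord-class] from
#'   [runConvergenceExperiment()].
#' @return A data.frame with one row per (function, optimizer): best, mean
#'   and sd of the final fitness over seeds.
#' @export
summarizeConvergence <- function(records) {
    key <- vapply(records, function(r)
        paste(r@functionName, r@optimizerName, sep = "/"), character(1))
    finals <- vapply(records, function(r) r@best, numeric(1))
    out <- do.call(rbind, lapply(split(seq_along(records), key), function(ii) {
        r <- records[[ii[1]]]
        data.frame(functionName = r@functionName,
                   optimizerName = r@optimizerName,
                   runs = length(ii),
                   best = min(finals[ii]),
                   mean = mean(finals[ii]),
                   sd = if (length(ii) > 1) sd(finals[ii]) else NA_real_)
    }))
    rownames(out) <- NULL
    out
}

#' Write convergence traces as CSV
#'
#' Long format: functionName, optimizerName, seed, generation, best.
#'
#' @param records list of [ConvergenceRecord-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeConvergenceTraces <- function(records, path) {
    rows <- lapply(records, function(r)
        data.frame(functionName = r@functionName,
                   optimizerName = r@optimizerName, seed = r@seed,
                   generation = seq_along(r@trace), best = r@trace))
    write.csv(do.call(rbind, rows), path, row.names = FALSE)
    invisible(path)
}
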