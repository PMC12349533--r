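## Shared internal helpers: argument checking, angle arithmetic, seed streams.

.assertFinite <- function(x, what) {
    if (!is.numeric(x) || any(!is.finite(x)))
        stop(what, " must be finite numeric", call. = FALSE)
    invisible(x)
}

.assertLength <- function(x, n, what) {
    if (length(x) != n)
        stop(what, " must have length ", n, call. = FALSE)
    invisible(x)
}

#' Wrap angles into (-180, 180]
#'
#' @param theta numeric vector of angles in degrees.
#' @return Angles reduced modulo 360 into the half-open interval (-180, 180].
#' @examples
#' wrapAngle(c(0, 190, -190, 180, -180, 540))
#' @export
wrapAngle <- function(theta) {
    .assertFinite(theta, "theta")
    w <- theta - 360 * round(theta / 360)
    w[w <= -180] <- w[w <= -180] + 360
    w
}

## shorter-arc absolute angular difference, in [0, 180]
.angleDiff <- function(a, b) {
    d <- abs(wrapAngle(a - b))
    d
}

#' Derive a per-stream seed from a global seed
#'
#' A single run seed is split deterministically into independent per-module
#' seeds (population initialization, phantom noise, image noise, ...) so that
#' changing the number of draws one stage consumes cannot shift another
#' stage's stream.
#'
#' @param seed integer global seed.
#' @param stream character stream label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' deriveSeed(1, "image-noise")
#' @export
deriveSeed <- function(seed, stream) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
    ## modular mix kept in double precision; all quantities < 2^53
    as.integer((abs(seed) * 48271 + h * 8191) %% 2147483646)
}

## clamp a numeric vector/matrix into [lo, hi]
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## quiet progress messages, enabled with options(DualPoseReg.verbose = TRUE)
.dprMessage <- function(...) {
    if (isTRUE(getOption("DualPoseReg.verbose", FALSE)))
        message(...)
    invisible(NULL)
}
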