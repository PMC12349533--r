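## Rigid transforms from 6-DOF poses, lateral-view composition, pose errors.

.rotX <- function(th) {
    c <- cos(th); s <- sin(th)
    matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
.rotY <- function(th) {
    c <- cos(th); s <- sin(th)
    matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
.rotZ <- function(th) {
    c <- cos(th); s <- sin(th)
    matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Build the rigid transform of a 6-DOF pose
#'
#' The rotation convention is fixed: extrinsic rotations about the world
#' axes composed as `R = Rz %*% Ry %*% Rx` (right-handed, angles in degrees),
#' applied about the pivot `center`, followed by the translation. A point `p`
#' maps to `R %*% (p - center) + center + t`.
#'
#' @param pose a [Pose-class].
#' @param center numeric(3) rotation pivot in world mm (typically the volume
#'   center, see [volumeCenter()]).
#' @return A [RigidTransform-class].
#' @examples
#' m <- poseMatrix(Pose(thetaZ = 90))
#' applyTransform(m, c(1, 0, 0))  # -> (0, 1, 0)
#' @export
poseMatrix <- function(pose, center = c(0, 0, 0)) {
    stopifnot(is(pose, "Pose"))
    .assertFinite(center, "center")
    .assertLength(center, 3, "center")
    th <- pose@angles * pi / 180
    R <- .rotZ(th[3]) %*% .rotY(th[2]) %*% .rotX(th[1])
    m <- diag(4)
    m[1:3, 1:3] <- R
    m[1:3, 4] <- center + pose@translation - R %*% center
    RigidTransform(m)
}

#' Compose the lateral-view transform
#'
#' Left-multiplies the frontal pose matrix with the fixed frontal-to-lateral
#' transform: `LateralMat = TransMat %*% FrontalMat`.
#'
#' @param frontal the frontal [RigidTransform-class].
#' @param trans the frontal-to-lateral [RigidTransform-class]
#'   (see [defaultTransMat()]).
#' @return A [RigidTransform-class].
#' @export
composeLateral <- function(frontal, trans) {
    stopifnot(is(frontal, "RigidTransform"), is(trans, "RigidTransform"))
    RigidTransform(trans@matrix %*% frontal@matrix)
}

#' Default frontal-to-lateral transform
#'
#' A +90 degree rotation about the world Y axis (the patient's longitudinal
#' axis). Applied to the volume via [composeLateral()] while keeping the
#' frontal camera, it produces the lateral view; the equivalent fixed-camera
#' formulation ([makeDefaultGeometry()] with `view = "lateral"`) has the
#' point source on the +X axis. Override when the scanner's frontal/lateral
#' relation differs.
#'
#' @param angle rotation about Y in degrees (default +90).
#' @return A [RigidTransform-class].
#' @export
defaultTransMat <- function(angle = 90) {
    poseMatrix(Pose(thetaY = angle), center = c(0, 0, 0))
}

#' Apply a rigid transform to points
#'
#' @param transform a [RigidTransform-class].
#' @param points numeric(3) or an N x 3 matrix of world points (mm).
#' @return Transformed points with the same shape as the input.
#' @export
applyTransform <- function(transform, points) {
    stopifnot(is(transform, "RigidTransform"))
    .assertFinite(points, "points")
    m <- transform@matrix
    if (is.matrix(points)) {
        stopifnot(ncol(points) == 3)
        t(m[1:3, 1:3] %*% t(points) + m[1:3, 4])
    } else {
        .assertLength(points, 3, "points")
        drop(m[1:3, 1:3] %*% points + m[1:3, 4])
    }
}

#' Invert a rigid transform
#'
#' Uses the closed form for rigid matrices: `R^-1 = R'`,
#' `t^-1 = -R' %*% t`.
#'
#' @param transform a [RigidTransform-class].
#' @return The inverse [RigidTransform-class].
#' @export
rigidInverse <- function(transform) {
    stopifnot(is(transform, "RigidTransform"))
    m <- transform@matrix
    R <- t(m[1:3, 1:3])
    inv <- diag(4)
    inv[1:3, 1:3] <- R
    inv[1:3, 4] <- -R %*% m[1:3, 4]
    RigidTransform(inv)
}

#' Per-axis pose error
#'
#' Component-wise absolute differences between two poses. Angular differences
#' take the shorter arc, so they lie in \[0, 180\] (e.g. 179 vs -179 degrees
#' is a 2 degree error). The measure is symmetric in its arguments.
#'
#' @param estimated,truth [Pose-class] objects.
#' @return A [PoseError-class].
#' @examples
#' e <- poseError(Pose(thetaZ = 179), Pose(thetaZ = -179))
#' rotationError(e)  # Z error is 2 degrees
#' @export
poseError <- function(estimated, truth) {
    stopifnot(is(estimated, "Pose"), is(truth, "Pose"))
    new("PoseError",
        rotation = .angleDiff(estimated@angles, truth@angles),
        translation = abs(estimated@translation - truth@translation))
}

## ---- serialization ----------------------------------------------------------

#' Pose and transform serialization
#'
#' Poses serialize to a 6-number vector ordered
#' (tX, tY, tZ, thetaX, thetaY, thetaZ) in (mm, mm, mm, deg, deg, deg);
#' transforms to a 16-number row-major vector. Both forms are what the
#' YAML/JSON run configurations use.
#'
#' @param pose a [Pose-class].
#' @param x a numeric vector (length 6 for poses, 16 for transforms).
#' @param transform a [RigidTransform-class].
#' @return `poseAsVector`/`transformAsVector` return numeric vectors;
#'   `poseFromVector`/`transformFromVector` rebuild the objects.
#' @name pose-serialization
NULL

#' @rdname pose-serialization
#' @export
poseAsVector <- function(pose) {
    stopifnot(is(pose, "Pose"))
    setNames(c(pose@translation, pose@angles),
             c("tX", "tY", "tZ", "thetaX", "thetaY", "thetaZ"))
}

#' @rdname pose-serialization
#' @export
poseFromVector <- function(x) {
    .assertLength(x, 6, "pose vector")
    Pose(x[1], x[2], x[3], x[4], x[5], x[6])
}

#' @rdname pose-serialization
#' @export
transformAsVector <- function(transform) {
    stopifnot(is(transform, "RigidTransform"))
    as.numeric(t(transform@matrix))
}

#' @rdname pose-serialization
#' @export
transformFromVector <- function(x) {
    .assertLength(x, 16, "transform vector")
    RigidTransform(matrix(as.numeric(x), 4, 4, byrow = TRUE))
}
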