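#' Rigid-body transform
#'
#' A proper rotation plus translation, the operator used to grow DED chains.
#' Coordinates are row vectors in Angstrom; the transform acts as
#' \code{x -> x R^T + t}.
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation Numeric 3-vector (Angstrom).
#' @return Object of class \code{"rigid_transform"}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L,
            all(is.finite(rotation)), all(is.finite(translation)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    stop("rotation must be orthonormal with det +1 (no reflections)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  s <- screw_decompose(x)
  cat(sprintf("rigid transform: twist %.2f deg, rise %.3f A about axis (%.3f, %.3f, %.3f)\n",
              s$twist, s$rise, s$axis[1], s$axis[2], s$axis[3]))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param op A [rigid_transform()].
#' @param coords n x 3 numeric matrix of positions (rows), or a domain
#'   data frame with columns \code{x}, \code{y}, \code{z}.
#' @return Transformed object of the same shape.
#' @export
apply_transform <- function(op, coords) {
  stopifnot(inherits(op, "rigid_transform"))
  if (is.data.frame(coords)) {
    xyz <- as.matrix(coords[c("x", "y", "z")])
    xyz <- xyz %*% t(op$rotation) + rep(op$translation, each = nrow(xyz))
    coords[c("x", "y", "z")] <- xyz
    return(coords)
  }
  coords %*% t(op$rotation) + rep(op$translation, each = nrow(coords))
}

#' Compose and invert rigid transforms
#'
#' \code{compose_transform(a, b)} returns the transform "apply b, then a".
#'
#' @param a,b,op [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(op) {
  rigid_transform(t(op$rotation), as.numeric(-t(op$rotation) %*% op$translation))
}

#' @rdname compose_transform
#' @param k Integer power (may be negative).
#' @export
transform_power <- function(op, k) {
  k <- as.integer(k)
  if (k < 0L) return(transform_power(invert_transform(op), -k))
  out <- rigid_transform()
  while (k > 0L) {
    out <- compose_transform(op, out)
    k <- k - 1L
  }
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired coordinates, via SVD of the cross-covariance with the standard
#' determinant correction, so a reflection is never returned even for
#' mirror-image inputs.
#'
#' @param moving n x 3 matrix (or domain data frame) to be transformed.
#' @param target n x 3 matrix (or domain data frame) to superpose onto;
#'   rows are paired with \code{moving}.
#' @return List with \code{transform} (a [rigid_transform()] mapping
#'   \code{moving} onto \code{target}) and \code{rmsd} (Angstrom).
#' @export
superpose <- function(moving, target) {
  X <- as_xyz(moving)
  Y <- as_xyz(target)
  if (nrow(X) != nrow(Y)) stop("superpose: point counts differ")
  if (nrow(X) < 3L) stop("superpose: need at least 3 paired positions")
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx)
  Yc <- sweep(Y, 2L, cy)
  # degenerate (collinear) configurations leave the rotation underdetermined
  if (svd(Xc, nu = 0, nv = 0)$d[2L] < 1e-8 * max(1, svd(Xc, nu = 0, nv = 0)$d[1L])) {
    stop("superpose: degenerate (collinear) point configuration")
  }
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cy - as.numeric(R %*% cx)
  op <- rigid_transform(R, t_vec)
  fitted <- apply_transform(op, X)
  list(transform = op,
       rmsd = sqrt(mean(rowSums((fitted - Y)^2))))
}

as_xyz <- function(coords) {
  if (is.data.frame(coords)) {
    m <- as.matrix(coords[c("x", "y", "z")])
  } else {
    m <- as.matrix(coords)
  }
  if (ncol(m) != 3L) stop("coordinates must have 3 columns")
  if (any(!is.finite(m))) stop("coordinates must be finite")
  unname(m)
}

#' Screw-axis decomposition of a rigid transform
#'
#' Every rigid transform is a rotation by a twist angle about a unique axis
#' combined with a rise along that axis (Chasles' theorem); repeated
#' application therefore traces a helix, which is how a repeated
#' domain-domain interface propagates into a chain with helical character.
#' For twists below \code{tol} the transform is reported as a pure
#' translation with the axis along the translation vector.
#'
#' @param op A [rigid_transform()].
#' @param tol Rotation-angle tolerance (radians) below which the transform
#'   is treated as a pure translation.
#' @return List with \code{axis} (unit 3-vector), \code{point} (a point on
#'   the axis, Angstrom), \code{twist} (degrees, in (-180, 180]), and
#'   \code{rise} (Angstrom per application along the axis).
#' @export
screw_decompose <- function(op, tol = 1e-9) {
  stopifnot(inherits(op, "rigid_transform"))
  R <- op$rotation
  t_vec <- op$translation
  cos_theta <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  theta <- acos(cos_theta)
  if (theta < tol) {
    # pure translation: axis along t (or z for the identity)
    len <- sqrt(sum(t_vec^2))
    axis <- if (len > 0) t_vec / len else c(0, 0, 1)
    return(list(axis = axis, point = c(0, 0, 0), twist = 0, rise = len))
  }
  if (abs(theta - pi) < 1e-6) {
    # 180-degree rotation: axis from the +1 eigenvector of R
    ev <- eigen(R, symmetric = FALSE)
    i <- which.min(abs(ev$values - 1))
    axis <- Re(ev$vectors[, i])
    axis <- axis / sqrt(sum(axis^2))
  } else {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(theta))
  }
  twist_sign <- 1
  rise <- sum(t_vec * axis)
  # canonical orientation: nonnegative rise; flipping the axis negates the twist
  if (rise < 0) {
    axis <- -axis
    rise <- -rise
    twist_sign <- -1
  }
  t_perp <- t_vec - rise * axis
  # solve (I - R) p = t_perp in the plane perpendicular to the axis
  A <- diag(3) - R
  sv <- svd(A)
  inv_d <- ifelse(sv$d > 1e-9, 1 / sv$d, 0)
  point <- as.numeric(sv$v %*% (inv_d * crossprod(sv$u, t_perp)))
  twist <- twist_sign * theta * 180 / pi
  if (twist <= -180) twist <- twist + 360
  list(axis = axis, point = point, twist = twist, rise = rise)
}

#' Rebuild a rigid transform from screw parameters
#'
#' Inverse of [screw_decompose()]: rotation by \code{twist} about the axis
#' through \code{point}, advanced by \code{rise} along the axis.
#'
#' @param screw List with \code{axis}, \code{point}, \code{twist} (degrees),
#'   \code{rise} (Angstrom).
#' @return A [rigid_transform()].
#' @export
screw_to_transform <- function(screw) {
  a <- screw$axis / sqrt(sum(screw$axis^2))
  theta <- screw$twist * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  p <- screw$point
  t_vec <- screw$rise * a + as.numeric((diag(3) - R) %*% p)
  rigid_transform(R, t_vec)
}

#' Rotation by an angle about an axis (helper constructor)
#'
#' @param axis 3-vector (normalized internally).
#' @param angle_deg Rotation angle in degrees.
#' @param translation Optional translation 3-vector.
#' @return A [rigid_transform()].
#' @export
rotation_about_axis <- function(axis, angle_deg, translation = c(0, 0, 0)) {
  op <- screw_to_transform(list(axis = axis, point = c(0, 0, 0),
                                twist = angle_deg, rise = 0))
  rigid_transform(op$rotation, translation)
}
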