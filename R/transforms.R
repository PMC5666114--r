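# Rigid-transformation algebra: the generator of every assembly in the package.
# Convention: transforms act on column vectors, x' = R x + t; Euler angles are
# intrinsic Z-Y-Z in degrees (a single package-wide constant, see euler_to_rotation).

EULER_CONVENTION <- "ZYZ-intrinsic-degrees"

#' Create a rigid transform
#'
#' A rigid transform is a proper rotation plus a translation, acting on
#' coordinates as `x' = R x + t` (coordinates in Angstrom). It is the
#' generator of helical and ring assemblies: applying the same transform
#' repeatedly places successive copies of a seed unit.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Numeric 3-vector, Angstrom.
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @examples
#' rigid_transform(rotation_about_z(60), c(0, 0, 3))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || anyNA(rotation)) {
    abort("`rotation` must be a 3x3 numeric matrix.")
  }
  if (length(translation) != 3L || anyNA(translation)) {
    abort("`translation` must be a numeric 3-vector.")
  }
  err_orth <- max(abs(crossprod(rotation) - diag(3)))
  if (err_orth > 1e-6) {
    abort(sprintf("`rotation` is not orthonormal (max |R'R - I| = %.3g).", err_orth))
  }
  if (det(rotation) < 0) {
    abort("`rotation` is improper (det = -1); reflections are not rigid motions.")
  }
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- tryCatch(rotation_angle(x$R), error = function(e) NA_real_)
  cat(sprintf("<rigid_transform> rotation %.3f deg, |t| = %.3f A\n", ang, sqrt(sum(x$t^2))))
  cat("Euler (ZYZ intrinsic, deg):", sprintf("%.4f", transform_to_euler(x)), "\n")
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Elementary rotations
#'
#' Rotation matrices about the coordinate axes, angle in degrees.
#'
#' @param angle Rotation angle, degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_z <- function(angle) {
  a <- angle * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' @rdname rotation_about_z
#' @export
rotation_about_y <- function(angle) {
  a <- angle * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rotation_about_z
#' @export
rotation_about_x <- function(angle) {
  a <- angle * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' Rotation about an arbitrary axis
#'
#' Rodrigues construction of the rotation by `angle` degrees about the unit
#' direction `axis`.
#'
#' @param axis Numeric 3-vector (normalized internally).
#' @param angle Degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  n <- axis / sqrt(sum(axis^2))
  a <- angle * pi / 180
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#'
#' @param R 3x3 rotation matrix.
#' @return Angle in degrees, in \[0, 180\].
#' @export
rotation_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Compose, invert and apply rigid transforms
#'
#' `compose_transform(a, b)` returns the transform that applies `b` first and
#' then `a` (so `apply_transform(compose_transform(a, b), x)` equals
#' `apply_transform(a, apply_transform(b, x))`). `invert_transform` returns the
#' inverse motion. `transform_power` composes a transform with itself `k`
#' times (`k = 0` gives the identity; negative `k` inverts first).
#'
#' @param a,b,x Rigid transforms.
#' @param k Integer power.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  stopifnot(is_rigid_transform(a), is_rigid_transform(b))
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(x) {
  stopifnot(is_rigid_transform(x))
  rigid_transform(t(x$R), as.numeric(-t(x$R) %*% x$t))
}

#' @rdname compose_transform
#' @export
transform_power <- function(x, k) {
  stopifnot(is_rigid_transform(x), k == round(k))
  if (k < 0) return(transform_power(invert_transform(x), -k))
  out <- identity_transform()
  for (i in seq_len(k)) out <- compose_transform(x, out)
  out
}

#' @rdname compose_transform
#' @export
identity_transform <- function() rigid_transform()

#' Apply a rigid transform to coordinates
#'
#' Moves points by `x' = R x + t`. Accepts a bare n x 3 matrix or an atom
#' tibble (any data frame with `x`, `y`, `z` columns); returns the same shape.
#'
#' @param transform A `rigid_transform`.
#' @param coords n x 3 matrix or data frame with columns `x`, `y`, `z`.
#' @return Transformed coordinates, same class as the input.
#' @export
apply_transform <- function(transform, coords) {
  stopifnot(is_rigid_transform(transform))
  if (is.data.frame(coords)) {
    m <- as.matrix(coords[, c("x", "y", "z")])
    m2 <- m %*% t(transform$R)
    coords$x <- m2[, 1] + transform$t[1]
    coords$y <- m2[, 2] + transform$t[2]
    coords$z <- m2[, 3] + transform$t[3]
    return(coords)
  }
  coords <- as.matrix(coords)
  sweep(coords %*% t(transform$R), 2, transform$t, "+")
}

#' Euler angles (intrinsic Z-Y-Z) to and from rotation matrices
#'
#' The package parameterizes the rotational part of the inter-unit transform
#' by intrinsic Z-Y-Z Euler angles in degrees:
#' `R = Rz(alpha) %*% Ry(beta) %*% Rz(gamma)`. At gimbal lock (`beta` within
#' 1e-6 deg of 0 or 180) the degeneracy is resolved by reporting `gamma = 0`
#' and folding the free angle into `alpha`.
#'
#' @param alpha,beta,gamma Euler angles, degrees.
#' @param transform A `rigid_transform` or bare 3x3 rotation matrix.
#' @return `euler_to_rotation` returns a 3x3 matrix; `transform_to_euler`
#'   returns a named numeric 3-vector (`alpha`, `beta`, `gamma`) in degrees.
#' @export
euler_to_rotation <- function(alpha, beta, gamma) {
  rotation_about_z(alpha) %*% rotation_about_y(beta) %*% rotation_about_z(gamma)
}

#' @rdname euler_to_rotation
#' @export
transform_to_euler <- function(transform) {
  R <- if (is_rigid_transform(transform)) transform$R else as.matrix(transform)
  sb <- sqrt(R[1, 3]^2 + R[2, 3]^2)
  if (sb < 1e-8) {
    # gimbal lock: beta 0 or 180, gamma fixed to 0 by convention
    if (R[3, 3] > 0) {
      alpha <- atan2(R[2, 1], R[1, 1])
      beta <- 0
    } else {
      alpha <- atan2(-R[2, 1], -R[1, 1])
      beta <- pi
    }
    gamma <- 0
  } else {
    alpha <- atan2(R[2, 3], R[1, 3])
    beta <- atan2(sb, R[3, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  }
  c(alpha = alpha, beta = beta, gamma = gamma) * 180 / pi
}

#' Build a transform from grid-search parameters
#'
#' The refinement grid is six-dimensional: three Z-Y-Z Euler angles (degrees)
#' and three translation components (Angstrom). This helper maps a parameter
#' vector to the corresponding `rigid_transform` and back.
#'
#' @param p Named numeric vector with `alpha`, `beta`, `gamma`, `tx`, `ty`, `tz`.
#' @param transform A `rigid_transform`.
#' @return `params_to_transform` a `rigid_transform`; `transform_to_params` a
#'   named 6-vector.
#' @export
params_to_transform <- function(p) {
  rigid_transform(euler_to_rotation(p[["alpha"]], p[["beta"]], p[["gamma"]]),
                  c(p[["tx"]], p[["ty"]], p[["tz"]]))
}

#' @rdname params_to_transform
#' @export
transform_to_params <- function(transform) {
  stopifnot(is_rigid_transform(transform))
  e <- transform_to_euler(transform)
  c(alpha = unname(e["alpha"]), beta = unname(e["beta"]), gamma = unname(e["gamma"]),
    tx = transform$t[1], ty = transform$t[2], tz = transform$t[3])
}

#' Serialize rigid transforms to and from JSON
#'
#' Transforms are exchanged as JSON records with the rotation in row-major
#' order and an explicit convention tag, so external tools can verify what
#' the angles mean.
#'
#' @param transform A `rigid_transform`.
#' @param path File path; `transform_to_json` returns the JSON string
#'   invisibly and writes to `path` when given.
#' @return `transform_from_json` returns a `rigid_transform`.
#' @export
transform_to_json <- function(transform, path = NULL) {
  stopifnot(is_rigid_transform(transform))
  rec <- list(rotation = as.numeric(t(transform$R)), translation = transform$t,
              convention = EULER_CONVENTION)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname transform_to_json
#' @export
transform_from_json <- function(path) {
  rec <- jsonlite::fromJSON(path)
  if (!is.null(rec$convention) && !identical(rec$convention, EULER_CONVENTION)) {
    abort(sprintf("Transform JSON uses convention '%s'; expected '%s'.",
                  rec$convention, EULER_CONVENTION))
  }
  rigid_transform(matrix(rec$rotation, 3, 3, byrow = TRUE), rec$translation)
}

#' Screw (helical) parameters of a rigid transform
#'
#' Any rigid transform with a non-trivial rotation is a screw motion: a
#' rotation by some angle about an axis plus a rise along that axis. For the
#' generator of a helical assembly the angle and rise are the helical
#' parameters: `units_per_turn = 360 / angle` and
#' `pitch = rise * units_per_turn`.
#'
#' The axis sign is chosen so the angle lies in (0, 180\]; the rise is the
#' signed projection of the translation on that axis. Near-identity rotations
#' (angle below 0.1 degree) have no defined axis and are rejected.
#'
#' @param transform A `rigid_transform`.
#' @return A list of class `helical_params`: `axis` (unit 3-vector),
#'   `angle_per_unit` (deg), `rise_per_unit` (A), `units_per_turn`, `pitch` (A).
#' @examples
#' screw_parameters(rigid_transform(rotation_about_z(360 / 7), c(0, 0, 2)))
#' @export
screw_parameters <- function(transform) {
  stopifnot(is_rigid_transform(transform))
  R <- transform$R
  angle <- rotation_angle(R)
  if (angle < 0.1) {
    abort("Rotation angle below 0.1 degree: screw axis is degenerate (pure translation).")
  }
  if (angle < 179.999) {
    # axis from the antisymmetric part, sign carries the rotation sense
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    ax <- ax / sqrt(sum(ax^2))
  } else {
    # 180 deg: antisymmetric part vanishes; use the +1 eigenvector
    ev <- eigen(R, symmetric = FALSE)
    i <- which.min(abs(ev$values - 1))
    ax <- Re(ev$vectors[, i])
    ax <- ax / sqrt(sum(ax^2))
    nz <- which(abs(ax) > 1e-8)[1]
    if (ax[nz] < 0) ax <- -ax
  }
  rise <- sum(transform$t * ax)
  structure(list(axis = ax, angle_per_unit = angle, rise_per_unit = rise,
                 units_per_turn = 360 / angle, pitch = rise * 360 / angle),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("<helical_params> %.3f deg/unit (%.3f units/turn), rise %.3f A, pitch %.3f A\n",
              x$angle_per_unit, x$units_per_turn, x$rise_per_unit, x$pitch))
  cat("axis:", sprintf("%.4f", x$axis), "\n")
  invisible(x)
}

# quaternion helpers for the twist-swing decomposition -------------------------

rotation_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

quat_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] + c(a[3] * b[4] - a[4] * b[3],
                                      a[4] * b[2] - a[2] * b[4],
                                      a[2] * b[3] - a[3] * b[2]))
}

quat_angle <- function(q) 2 * acos(min(1, abs(q[1]))) * 180 / pi

#' Twist-swing (shear-hinge) decomposition of a rotation
#'
#' Splits the rotational part of a transform into a *twist* about a given
#' main axis composed with a *swing* about an axis perpendicular to it:
#' `R = R_swing %*% R_twist`. In comparisons of dimer orientation between a
#' helical assembly and a reference ring, the twist is the shearing of the
#' two protomers about the main (helix/ring) axis and the swing is the
#' closing hinge motion about a perpendicular axis.
#'
#' @param transform A `rigid_transform` (only its rotation is used) or a 3x3
#'   rotation matrix.
#' @param main_axis Direction of the main axis (normalized internally).
#' @return A list of class `rotation_decomposition`: `total_angle`,
#'   `twist_angle`, `swing_angle` (degrees, all in \[0, 180\]), `main_axis`,
#'   and the two factor rotations `R_twist`, `R_swing`.
#' @export
decompose_rotation <- function(transform, main_axis) {
  R <- if (is_rigid_transform(transform)) transform$R else as.matrix(transform)
  n <- main_axis / sqrt(sum(main_axis^2))
  q <- rotation_to_quat(R)
  proj <- sum(q[2:4] * n)
  tw <- c(q[1], proj * n)
  ntw <- sqrt(sum(tw^2))
  if (ntw < 1e-12) {
    # 180 deg rotation about an axis perpendicular to n: pure swing
    q_twist <- c(1, 0, 0, 0)
  } else {
    q_twist <- tw / ntw
  }
  q_swing <- quat_multiply(q, c(q_twist[1], -q_twist[2:4]))
  structure(list(
    total_angle = quat_angle(q),
    twist_angle = quat_angle(q_twist),
    swing_angle = quat_angle(q_swing),
    main_axis = n,
    R_twist = quat_to_rotation(q_twist),
    R_swing = quat_to_rotation(q_swing)), class = "rotation_decomposition")
}

#' @export
print.rotation_decomposition <- function(x, ...) {
  cat(sprintf("<rotation_decomposition> total %.2f deg = swing %.2f (hinge) o twist %.2f (shear)\n",
              x$total_angle, x$swing_angle, x$twist_angle))
  invisible(x)
}
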