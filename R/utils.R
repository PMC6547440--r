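ddeg <- function(x) x * 180 / pi
drad <- function(x) x * pi / 180

rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary axis
#'
#' @param axis numeric length-3 axis (need not be normalized).
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_axis <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(theta); s <- sin(theta)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + s * K + (1 - c) * (K %*% K)
}

is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

vnorm <- function(v) sqrt(sum(v^2))

#' Random proper rotation (for tests and spot checks)
#' @keywords internal
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z),     2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2),     2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x),     1 - 2 * (x^2 + y^2)), 3, 3)
}

# --- mid-frame (CEHS-style) composition and decomposition -------------------
#
# A rigid step is parameterized by three translations d = (d1, d2, d3) and
# three rotations (theta1 about x, theta2 about y, theta3 about z), degrees/Å.
# The rotation from frame 1 to frame 2 is
#   R = Rz(w/2 - phi) Ry(gamma) Rz(w/2 + phi)
# with gamma = sqrt(theta1^2 + theta2^2) (the bend), phi = atan2(theta1, theta2)
# and w = theta3.  The translation is expressed in the mid-frame
#   Tm = T1 Rz(w/2 - phi) Ry(gamma/2) Rz(phi).
# This scheme is exactly self-inverse, which the builder/analyzer round-trip
# tests rely on.

#' Compose a frame step from six rigid-body parameters
#'
#' @param frame1 3x3 rotation (columns x,y,z of the starting triad).
#' @param origin1 origin of the starting triad, Å.
#' @param par named or positional numeric vector: translations (Å) along the
#'   mid-frame x,y,z then rotations (degrees) about x,y,z.
#' @return list with `frame`, `origin` of the stepped triad and `mid_frame`,
#'   `mid_origin` of the mid-step triad.
#' @keywords internal
step_compose <- function(frame1, origin1, par) {
  d <- par[1:3]
  th1 <- drad(par[4]); th2 <- drad(par[5]); th3 <- drad(par[6])
  gamma <- sqrt(th1^2 + th2^2)
  phi <- if (gamma > 0) atan2(th1, th2) else 0
  R <- rot_z(th3 / 2 - phi) %*% rot_y(gamma) %*% rot_z(th3 / 2 + phi)
  Tm <- frame1 %*% rot_z(th3 / 2 - phi) %*% rot_y(gamma / 2) %*% rot_z(phi)
  frame2 <- frame1 %*% R
  origin2 <- origin1 + as.vector(Tm %*% d)
  list(frame = frame2, origin = origin2, mid_frame = Tm,
       mid_origin = origin1 + as.vector(Tm %*% d) / 2)
}

#' Decompose the rigid step between two triads into six parameters
#'
#' Exact inverse of [step_compose()]. Angles returned in degrees in
#' (-180, 180], translations in Å in the mid-frame.
#'
#' @return list with `par` (length 6: d1, d2, d3, theta1, theta2, theta3),
#'   `mid_frame`, `mid_origin`.
#' @keywords internal
step_decompose <- function(frame1, origin1, frame2, origin2) {
  z1 <- frame1[, 3]; z2 <- frame2[, 3]
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  cz <- cross3(z1, z2)
  gamma <- atan2(vnorm(cz), sum(z1 * z2))
  if (vnorm(cz) < 1e-9) {
    if (sum(z1 * z2) < 0)
      stop("bend of 180 degrees: hinge axis undefined")
    # no bend: pure twist about the common z
    x1 <- frame1[, 1]; x2 <- frame2[, 1]
    w <- atan2(sum(cross3(x1, x2) * z1), sum(x1 * x2))
    Tm <- frame1 %*% rot_z(w / 2)
    th1 <- th2 <- 0
  } else {
    # hinge-axis scheme: the signed hinge direction removes the branch
    # ambiguity of Euler-angle extraction at zero twist
    hinge <- cz / vnorm(cz)
    F1 <- rot_axis(hinge, gamma / 2) %*% frame1
    F2 <- rot_axis(hinge, -gamma / 2) %*% frame2
    zm <- F1[, 3]
    x1 <- F1[, 1]; x2 <- F2[, 1]
    w <- atan2(sum(cross3(x1, x2) * zm), sum(x1 * x2))
    xm <- x1 + x2
    if (vnorm(xm) < 1e-9)
      stop("twist of 180 degrees: mid-frame undefined")
    xm <- xm / vnorm(xm)
    ym <- cross3(zm, xm)
    Tm <- cbind(xm, ym, zm)
    phi <- atan2(sum(cross3(hinge, ym) * zm), sum(hinge * ym))
    th1 <- gamma * sin(phi)
    th2 <- gamma * cos(phi)
  }
  d <- as.vector(crossprod(Tm, origin2 - origin1))
  list(par = c(d, ddeg(c(th1, th2, w))), mid_frame = Tm,
       mid_origin = (origin1 + origin2) / 2)
}

#' Place two triads symmetrically about a given mid-frame
#'
#' Inverse-direction helper used by the duplex builder: given the pair
#' (mid) frame and six parameters, returns the two flanking triads such that
#' [step_decompose()] from the first to the second recovers the parameters
#' and their mid-frame is the given one.
#' @keywords internal
step_split <- function(mid_frame, mid_origin, par) {
  d <- par[1:3]
  th1 <- drad(par[4]); th2 <- drad(par[5]); th3 <- drad(par[6])
  gamma <- sqrt(th1^2 + th2^2)
  phi <- if (gamma > 0) atan2(th1, th2) else 0
  Hm <- rot_z(th3 / 2 - phi) %*% rot_y(gamma / 2) %*% rot_z(phi)
  frame1 <- mid_frame %*% t(Hm)
  R <- rot_z(th3 / 2 - phi) %*% rot_y(gamma) %*% rot_z(th3 / 2 + phi)
  frame2 <- frame1 %*% R
  dv <- as.vector(mid_frame %*% d)
  list(frame1 = frame1, origin1 = mid_origin - dv / 2,
       frame2 = frame2, origin2 = mid_origin + dv / 2)
}
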