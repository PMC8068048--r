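# Core 3D primitives: planes, lines, rigid transforms, total-least-squares
# line fits, Kabsch registration and screw-axis (Chasles) decomposition.
# All distances are in mm, all angles in degrees.

# ---- classed error helpers -------------------------------------------------

aj_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "asymjaw_error")))
}

#' @keywords internal
vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-12) aj_stop("degenerate_geometry", paste("zero-length", what))
  v / n
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

#' Construct a 3D point
#'
#' Points are plain numeric length-3 vectors (x, y, z) in mm; this helper
#' only validates.
#'
#' @param x,y,z finite coordinates in mm.
#' @return numeric length-3 vector.
#' @export
point3 <- function(x, y, z) {
  p <- c(x, y, z)
  if (!all(is.finite(p))) aj_stop("degenerate_geometry", "non-finite point coordinates")
  p
}

#' Construct a plane from unit normal and offset
#'
#' The plane is the locus `normal . p == offset`.
#'
#' @param normal length-3 vector, normalized internally.
#' @param offset scalar offset in mm.
#' @return object of class `plane3` with fields `normal` (unit) and `offset`.
#' @export
plane3 <- function(normal, offset) {
  n <- unitize(normal, "plane normal")
  structure(list(normal = n, offset = offset / vnorm(normal)), class = "plane3")
}

#' Construct a line from point and direction
#'
#' @param point length-3 point on the line.
#' @param direction length-3 direction, normalized internally.
#' @return object of class `line3` with fields `point`, `direction` (unit).
#' @export
line3 <- function(point, direction) {
  structure(list(point = as.numeric(point),
                 direction = unitize(direction, "line direction")),
            class = "line3")
}

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation length-3 vector in mm.
#' @return object of class `rigid3`.
#' @export
rigid3 <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  R <- unname(as.matrix(rotation))
  dimnames(R) <- NULL
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    aj_stop("degenerate_geometry", "rotation must be proper orthonormal")
  structure(list(R = R, t = unname(as.numeric(translation))), class = "rigid3")
}

# internal constructor for transforms known to be valid (hot paths)
new_rigid3 <- function(R, t) structure(list(R = R, t = t), class = "rigid3")

#' Apply a rigid transform to points
#'
#' @param tf `rigid3` transform.
#' @param pts length-3 vector or n x 3 matrix.
#' @return transformed points, same shape as input.
#' @export
apply_rigid <- function(tf, pts) {
  if (is.matrix(pts)) sweep(pts %*% t(tf$R), 2, -tf$t) else drop(tf$R %*% pts) + tf$t
}

#' Compose rigid transforms (first applies `b`, then `a`)
#' @param a,b `rigid3` transforms.
#' @return `rigid3` equal to `a %o% b`.
#' @export
compose_rigid <- function(a, b) new_rigid3(a$R %*% b$R, drop(a$R %*% b$t) + a$t)

#' Invert a rigid transform
#' @param tf `rigid3` transform.
#' @return inverse `rigid3`.
#' @export
invert_rigid <- function(tf) new_rigid3(t(tf$R), drop(-t(tf$R) %*% tf$t))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Plane through three points
#'
#' Normal orientation follows the right-hand rule on (p2 - p1, p3 - p1).
#'
#' @param p1,p2,p3 length-3 points, pairwise distinct and non-collinear.
#' @return `plane3`.
#' @export
plane_from_points <- function(p1, p2, p3) {
  n <- cross3(p2 - p1, p3 - p1)
  if (vnorm(n) / 2 <= 1e-6)  # triangle area in mm^2
    aj_stop("degenerate_geometry", "points are collinear or coincident")
  n <- n / vnorm(n)
  plane3(n, sum(n * p1))
}

#' Signed point-plane distance
#'
#' Positive on the side the normal points toward.
#'
#' @param p length-3 point or n x 3 matrix.
#' @param plane `plane3`.
#' @return signed distance(s) in mm.
#' @export
signed_distance <- function(p, plane) {
  if (is.matrix(p)) drop(p %*% plane$normal) - plane$offset
  else sum(p * plane$normal) - plane$offset
}

#' Orthogonal projection of a point onto a plane
#' @param p length-3 point.
#' @param plane `plane3`.
#' @return projected point.
#' @export
project_to_plane <- function(p, plane) p - signed_distance(p, plane) * plane$normal

#' Angle between a line and a plane
#'
#' Reported in `[0, 90]` degrees: 0 when the line is parallel to the plane,
#' 90 when it is along the normal.
#'
#' @param line `line3`.
#' @param plane `plane3`.
#' @return angle in degrees.
#' @export
angle_line_plane <- function(line, plane) {
  s <- abs(sum(line$direction * plane$normal))
  deg(asin(min(1, s)))
}

#' Total-least-squares 3D line fit
#'
#' First principal direction through the centroid; rotation invariant,
#' unlike a y-on-x regression.
#'
#' @param pts n x 3 matrix, n >= `min_points`, not all coincident.
#' @param min_points minimum number of points (default 3).
#' @return `line3` with attribute `rms_residual` (root-mean-square
#'   perpendicular distance, mm).
#' @export
fit_line <- function(pts, min_points = 3) {
  pts <- rbind(pts)
  if (nrow(pts) < min_points)
    aj_stop("degenerate_geometry", sprintf("need at least %d points", min_points))
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  if (max(abs(X)) < 1e-12)
    aj_stop("degenerate_geometry", "all points coincide")
  ev <- eigen(crossprod(X), symmetric = TRUE)
  d <- ev$vectors[, 1]
  # deterministic sign: largest-magnitude component positive
  d <- d * sign(d[which.max(abs(d))])
  res <- sqrt(max(0, (sum(X^2) - ev$values[1]) / nrow(pts)))
  out <- line3(ctr, d)
  attr(out, "rms_residual") <- res
  out
}

#' Least-squares rigid registration (Kabsch)
#'
#' Finds the rotation + translation (no scaling) minimizing
#' `sum | T(ref_i) - cur_i |^2` over paired markers.
#'
#' @param ref,cur n x 3 matrices of paired points, n >= 3, `ref` non-collinear.
#' @return `rigid3` mapping `ref` onto `cur`.
#' @export
estimate_rigid_transform <- function(ref, cur) {
  ref <- rbind(ref); cur <- rbind(cur)
  if (nrow(ref) != nrow(cur)) aj_stop("degenerate_geometry", "marker counts differ")
  if (nrow(ref) < 3) aj_stop("degenerate_geometry", "need at least 3 markers")
  cr <- colMeans(ref); cc <- colMeans(cur)
  A <- sweep(ref, 2, cr); B <- sweep(cur, 2, cc)
  sv <- svd(A, nu = 0, nv = 3)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    aj_stop("degenerate_geometry", "reference markers are collinear")
  H <- crossprod(A, B)
  s <- svd(H)
  S <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% S %*% t(s$u)
  rigid3(R, cc - drop(R %*% cr))
}

rotation_angle_deg <- function(R) {
  deg(acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))))
}

#' Screw-axis (Chasles) decomposition of a rigid transform
#'
#' Returns the rotation axis of the transform as a `line3` whose point is the
#' axis point closest to the origin, with attributes `angle` (degrees) and
#' `slide` (translation along the axis, mm).
#'
#' @param tf `rigid3` with rotation angle at least `angle_floor`.
#' @param angle_floor minimum rotation angle (degrees) for a well-conditioned
#'   axis; default 1.
#' @return `line3` with attributes `angle` and `slide`.
#' @export
screw_axis <- function(tf, angle_floor = 1) {
  theta <- rotation_angle_deg(tf$R)
  if (theta < angle_floor)
    aj_stop("near_identity_rotation",
            sprintf("rotation angle %.4g deg below floor %.4g deg", theta, angle_floor))
  sk <- c(tf$R[3, 2] - tf$R[2, 3], tf$R[1, 3] - tf$R[3, 1], tf$R[2, 1] - tf$R[1, 2])
  if (theta < 175) {
    # |sk| = 2 sin(theta); oriented so rotation about d is positive
    d <- sk / vnorm(sk)
    slide <- sum(tf$t * d)
    tperp <- tf$t - slide * d
    # closed-form solution of (I - R) p = t_perp on the axis-orthogonal plane
    p <- 0.5 * (tperp + cross3(d, tperp) / tan(rad(theta) / 2))
  } else {
    # near half-turn: skew part degenerates, use the eigen decomposition
    ev <- eigen(tf$R)
    i <- which.min(abs(ev$values - 1))
    d <- unitize(Re(ev$vectors[, i]))
    if (sum(sk * d) < 0) d <- -d
    slide <- sum(tf$t * d)
    tperp <- tf$t - slide * d
    Q <- svd(diag(3) - tf$R)
    dinv <- ifelse(Q$d > 1e-9, 1 / Q$d, 0)
    p <- drop(Q$v %*% (dinv * crossprod(Q$u, tperp)))
  }
  p <- p - sum(p * d) * d   # canonical representative closest to origin
  out <- line3(p, d)
  attr(out, "angle") <- theta
  attr(out, "slide") <- slide
  out
}

# closed-form total-least-squares direction of 2D points (principal axis of
# the covariance), returned as a unit (h, v) vector
tls_dir2 <- function(h, v) {
  mh <- mean(h); mv <- mean(v)
  a <- sum((h - mh)^2); cc <- sum((v - mv)^2); b <- sum((h - mh) * (v - mv))
  ang <- 0.5 * atan2(2 * b, a - cc)
  c(cos(ang), sin(ang))
}

#' Rotation matrix about a unit axis (Rodrigues)
#' @param axis length-3 axis (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- unitize(axis); th <- rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Screw motion about an axis through a point
#'
#' Rotation by `angle_deg` about the axis through `point` along `axis`,
#' composed with translation `slide` along the axis.
#'
#' @param point,axis axis anchor point and direction.
#' @param angle_deg rotation angle (degrees).
#' @param slide translation along the axis (mm).
#' @return `rigid3`.
#' @export
screw_transform <- function(point, axis, angle_deg, slide = 0) {
  u <- unitize(axis)
  R <- rotation_about_axis(u, angle_deg)
  t <- point - drop(R %*% point) + slide * u
  new_rigid3(R, t)
}

# exp of a twist (w, v): constant-twist motion evaluated at s in [0, 1].
# w is the full rotation vector (rad), v the full translation parameter.
twist_pose <- function(w, v, s) {
  th <- vnorm(w) * s
  if (vnorm(w) < 1e-12) return(new_rigid3(diag(3), v * s))
  u <- w / vnorm(w)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  # V(s) integral for se(3) exponential
  V <- diag(3) * s + ((1 - cos(th)) / vnorm(w)) * K +
    ((th - sin(th)) / vnorm(w)) * (K %*% K)
  new_rigid3(R, drop(V %*% v))
}

# 2D helpers used by the measurement modules -------------------------------

# intersection of two 2D lines given by (point, direction)
intersect_lines2 <- function(p1, d1, p2, d2) {
  A <- cbind(d1, -d2)
  if (abs(det(A)) < 1e-12) aj_stop("degenerate_geometry", "parallel chords")
  s <- solve(A, p2 - p1)
  p1 + s[1] * d1
}

# minimum distance from 2D point to polyline (ordered vertices, n x 2)
point_polyline_dist2 <- function(p, poly) {
  best <- Inf; bestpt <- poly[1, ]
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    ab <- b - a; L2 <- sum(ab^2)
    t <- if (L2 < 1e-18) 0 else max(0, min(1, sum((p - a) * ab) / L2))
    q <- a + t * ab
    d <- sqrt(sum((p - q)^2))
    if (d < best) { best <- d; bestpt <- q }
  }
  list(dist = best, point = bestpt)
}

# angle of a projected 2D segment in (0, 180], measured from +h axis toward +v
projected_angle2 <- function(dh, dv) {
  a <- deg(atan2(dv, dh))
  if (a <= 0) a <- a + 180
  if (a > 180) a <- a - 180
  a
}
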