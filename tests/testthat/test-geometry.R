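test_that("plane construction matches the cross-product normal and flags degeneracy", {
  pl <- plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(pl$normal, c(0, 0, 1))
  expect_equal(pl$offset, 0)
  expect_error(plane_from_points(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               class = "degenerate_geometry")
  set.seed(11)
  for (i in 1:20) {
    p1 <- rnorm(3, 0, 10); p2 <- rnorm(3, 0, 10); p3 <- rnorm(3, 0, 10)
    n_oracle <- asymjaw:::cross3(p2 - p1, p3 - p1)
    n_oracle <- n_oracle / sqrt(sum(n_oracle^2))
    pl <- plane_from_points(p1, p2, p3)
    expect_equal(pl$normal, n_oracle, tolerance = 1e-12)
    expect_lt(max(abs(signed_distance(rbind(p1, p2, p3), pl))), 1e-9)
  }
})

test_that("signed distance is the Euclidean point-plane distance with a sign", {
  pl <- plane3(c(0, 0, 1), 0)
  expect_equal(signed_distance(c(5, 5, 3), pl), 3)
  expect_equal(signed_distance(c(5, 5, 0), pl), 0)
  set.seed(12)
  for (i in 1:10) {
    pl <- plane_from_points(rnorm(3, 0, 5), rnorm(3, 0, 5), rnorm(3, 0, 5))
    p <- rnorm(3, 0, 10)
    # grid-minimization oracle: dense lattice of plane points around the foot
    foot <- project_to_plane(p, pl)
    u <- asymjaw:::unitize(asymjaw:::cross3(pl$normal, pl$normal + c(1, 2, 3)))
    v <- asymjaw:::cross3(pl$normal, u)
    g <- as.matrix(expand.grid(seq(-2, 2, length.out = 41),
                               seq(-2, 2, length.out = 41)))
    q <- sweep(g[, 1] %o% u + g[, 2] %o% v, 2, -foot)
    dmin <- sqrt(min(rowSums(sweep(q, 2, p)^2)))
    expect_equal(abs(signed_distance(p, pl)), dmin, tolerance = 1e-9)
    expect_lt(abs(signed_distance(project_to_plane(p, pl), pl)), 1e-9)
  }
})

test_that("line-plane angle covers parallel, normal and oblique cases", {
  pl <- plane3(c(0, 0, 1), 0)
  expect_equal(angle_line_plane(line3(c(0, 0, 0), c(1, 0, 0)), pl), 0)
  expect_equal(angle_line_plane(line3(c(0, 0, 0), c(0, 0, 1)), pl), 90)
  expect_equal(angle_line_plane(line3(c(0, 0, 0), c(1, 0, 1)), pl), 45)
})

test_that("total-least-squares line fit is exact on lines and optimal on clouds", {
  d <- asymjaw:::unitize(c(2, -1, 3))
  pts <- outer(seq(-5, 5, 1), d) + rep(c(1, 2, 3), each = 11)
  ln <- fit_line(pts)
  expect_lt(min(sum((ln$direction - d)^2), sum((ln$direction + d)^2)), 1e-18)
  expect_lt(attr(ln, "rms_residual"), 1e-9)
  # mirrored clouds about a line: fitted direction equals the mirror axis
  off <- 0.4 * cbind(0, c(1, -1, 2, -2), c(-1, 1, -2, 2))
  pts2 <- rbind(outer(c(2, 4, 6, 8), c(1, 0, 0)) + off,
                outer(c(2, 4, 6, 8), c(1, 0, 0)) - off)
  ln2 <- fit_line(pts2)
  expect_equal(abs(ln2$direction[1]), 1, tolerance = 1e-12)
  # residual is minimal over random candidate lines through the centroid
  set.seed(13)
  cloud <- matrix(rnorm(60, 0, 2), 20, 3) + outer(seq(0, 19), c(1, 0.5, -0.2))
  ln3 <- fit_line(cloud)
  res <- function(dir) {
    X <- sweep(cloud, 2, colMeans(cloud))
    sqrt(mean(rowSums(X^2) - drop(X %*% dir)^2))
  }
  cand <- replicate(1000, res(random_unit()))
  expect_lte(attr(ln3, "rms_residual"), min(cand) + 1e-12)
  expect_error(fit_line(rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))),
               class = "degenerate_geometry")
})

test_that("rigid registration recovers exact motions and rejects collinear refs", {
  set.seed(14)
  ref <- matrix(rnorm(15, 0, 20), 5, 3)
  expect_equal(estimate_rigid_transform(ref, ref)$R, diag(3), tolerance = 1e-12)
  for (i in 1:25) {
    tf <- random_rigid_tf()
    cur <- apply_rigid(tf, ref)
    est <- estimate_rigid_transform(ref, cur)
    expect_lt(max(abs(est$R - tf$R)), 1e-9)
    expect_lt(max(abs(est$t - tf$t)), 1e-9)
  }
  bad <- outer(1:3, c(1, 1, 0))
  expect_error(estimate_rigid_transform(bad, bad), class = "degenerate_geometry")
})

test_that("screw decomposition recovers axis, angle and slide", {
  s <- screw_axis(screw_transform(c(0, 0, 0), c(0, 0, 1), 30))
  expect_equal(abs(s$direction[3]), 1, tolerance = 1e-12)
  expect_equal(attr(s, "angle"), 30, tolerance = 1e-9)
  expect_error(screw_axis(rigid3()), class = "near_identity_rotation")
  set.seed(15)
  for (i in 1:30) {
    ax <- random_unit(); p0 <- rnorm(3, 0, 25)
    th <- runif(1, 2, 170); sl <- rnorm(1)
    s <- screw_axis(screw_transform(p0, ax, th, sl))
    expect_lt(min(sum((s$direction - ax)^2), sum((s$direction + ax)^2)), 1e-12)
    expect_equal(attr(s, "angle"), th, tolerance = 1e-6)
    p_can <- p0 - sum(p0 * ax) * ax
    expect_lt(sqrt(sum((s$point - p_can)^2)), 1e-6)
  }
})

test_that("screw axis of a squared transform keeps the axis and doubles the angle", {
  set.seed(16)
  for (i in 1:15) {
    tf <- screw_transform(rnorm(3, 0, 20), random_unit(), runif(1, 3, 85), rnorm(1))
    s1 <- screw_axis(tf)
    s2 <- screw_axis(compose_rigid(tf, tf))
    expect_lt(min(sum((s1$direction - s2$direction)^2),
                  sum((s1$direction + s2$direction)^2)), 1e-12)
    expect_equal(attr(s2, "angle"), 2 * attr(s1, "angle"), tolerance = 1e-6)
    expect_lt(sqrt(sum((s1$point - s2$point)^2)), 1e-6)
  }
})

test_that("batch compiled registration agrees with the reference implementation", {
  set.seed(17)
  ref <- matrix(rnorm(15, 0, 25), 5, 3)
  for (i in 1:20) {
    cur <- apply_rigid(random_rigid_tf(), ref) + matrix(rnorm(15, 0, 0.05), 5, 3)
    tf <- estimate_rigid_transform(ref, cur)
    out <- asymjaw:::cpp_kabsch_poses(matrix(as.vector(t(cur)), 1), ref)
    expect_lt(max(abs(matrix(out$R9[1, ], 3, 3, byrow = TRUE) - tf$R)), 1e-10)
    expect_lt(max(abs(out$T[1, ] - tf$t)), 1e-10)
  }
})
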