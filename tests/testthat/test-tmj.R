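# circle/ellipse outlines and spherical joints built in code

circle_outline <- function(center, r, z, n = 24) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(t), center[2] + r * sin(t), z)
}

test_that("condylar centre is the chord intersection (circle, ellipse, irregular)", {
  geom <- condyle_geometry("L", medial_pole = c(3, -6, 0), lateral_pole = c(3, 14, 0),
                           axial_outline = circle_outline(c(3, 4), 10, 0),
                           highest_point = c(3, 4, 7))
  expect_equal(condyle_center(geom), c(3, 4, 0), tolerance = 1e-9)
  # irregular convex outline: oracle = exhaustive chord search over vertex pairs
  set.seed(41)
  t <- sort(runif(16, 0, 2 * pi))
  O <- cbind(2 + (8 + rnorm(16, 0, 0.3)) * cos(t), -1 + (6 + rnorm(16, 0, 0.3)) * sin(t), 0)
  med <- O[which.min(O[, 2]), ]; lat <- O[which.max(O[, 2]), ]
  gi <- condyle_geometry("L", med, lat, O, c(2, -1, 7))
  cc <- condyle_center(gi)
  dirp <- (lat - med)[1:2]; dirp <- dirp / sqrt(sum(dirp^2))
  perp <- c(-dirp[2], dirp[1])
  chord_pair <- function(u) {
    pr <- O[, 1:2] %*% u
    c(which.max(pr), which.min(pr))
  }
  i <- chord_pair(dirp); j <- chord_pair(perp)
  oracle <- asymjaw:::intersect_lines2(O[i[1], 1:2],
                                       O[i[1], 1:2] - O[i[2], 1:2],
                                       O[j[1], 1:2],
                                       O[j[1], 1:2] - O[j[2], 1:2])
  expect_equal(cc[1:2], oracle, tolerance = 1e-9)
})

test_that("condylar posture reads off the canonical coordinates", {
  expect_equal(unname(condylar_posture(c(13, 52, -8.7))), c(13, 52, 8.7))
  expect_equal(unname(condylar_posture(c(13, 0, -8.7))[2]), 0)
})

test_that("joint spaces of spherical condyle under spherical fossa are the gaps", {
  mk_joint <- function(shift_y = 0) {
    ctr <- c(10, 50, -10)
    cond <- ctr + c(0, shift_y, 0)
    # wall profiles: dense arcs of the R = 10 fossa sphere about ctr
    t <- seq(-0.5, 0.5, length.out = 31)
    wall_ant <- cbind(ctr[1] + 10 * cos(t), ctr[2], ctr[3] + 10 * sin(t))
    wall_post <- cbind(ctr[1] - 10 * cos(t), ctr[2], ctr[3] + 10 * sin(t))
    wall_med <- cbind(ctr[1], ctr[2] - 10 * cos(t), ctr[3] + 10 * sin(t))
    wall_lat <- cbind(ctr[1], ctr[2] + 10 * cos(t), ctr[3] + 10 * sin(t))
    fossa <- fossa_geometry("L", roof_point = ctr + c(0, 0, 10),
                            wall_profiles = list(anterior = wall_ant,
                                                 posterior = wall_post,
                                                 medial = wall_med,
                                                 lateral = wall_lat))
    cond_geom <- condyle_geometry("L",
                                  medial_pole = cond + c(0, -8, 0),
                                  lateral_pole = cond + c(0, 8, 0),
                                  axial_outline = circle_outline(cond[1:2], 8, cond[3]),
                                  highest_point = cond + c(0, 0, 8))
    list(cond = cond_geom, fossa = fossa)
  }
  j <- mk_joint()
  js <- joint_spaces(j$cond, j$fossa, sector_deg = 89)
  # tolerance reflects the chordal sagitta of the sampled fossa arcs
  expect_equal(unname(js), rep(2, 5), tolerance = 5e-4)
  # 1 mm medial shift (medial = -y for the left side)
  j2 <- mk_joint(shift_y = -1)
  js2 <- joint_spaces(j2$cond, j2$fossa, sector_deg = 89)
  expect_equal(unname(js2[c("MJS", "LJS", "SJS")]), c(1, 3, 2), tolerance = 5e-4)
})

test_that("joint spaces match a dense-sampling nearest-distance oracle", {
  set.seed(42)
  sk <- default_skull()
  lm <- to_chs(sk$landmarks, build_head_frame(sk$landmarks))
  cond <- asymjaw:::condyle_from_landmarks(lm, "_L")
  foss <- asymjaw:::fossa_from_landmarks(lm, "_L")
  js <- joint_spaces(cond, foss)
  O <- cond$axial_outline
  pA <- O[which.max(O[, 1]), c(1, 3)]
  W <- foss$wall_profiles$anterior[, c(1, 3)]
  dense <- do.call(rbind, lapply(seq_len(nrow(W) - 1), function(i)
    outer(1 - seq(0, 1, 0.001), W[i, ]) + outer(seq(0, 1, 0.001), W[i + 1, ])))
  oracle <- sqrt(min(rowSums(sweep(dense, 2, pA)^2)))
  expect_equal(unname(js["AJS"]), oracle, tolerance = 1e-6)
})

test_that("joint spaces respond linearly to small condylar translations", {
  # with minimal-gap spaces the sensitivity to a translation is its component
  # along the wall normal: delta * sin(wall steepness) for an in-plane shift
  sk <- default_skull(seed = 12, world_pose = FALSE)
  base <- measure_morphometry(sk$landmarks)$params
  lm <- sk$landmarks
  shift <- function(lm, d3) {
    lm$profiles[["condyle_axial_L"]] <- sweep(lm$profiles[["condyle_axial_L"]], 2, -d3)
    for (nm in c("CondMed_L", "CondLat_L", "Co_L"))
      lm$points[nm, ] <- lm$points[nm, ] + d3
    lm
  }
  gain_m <- sin(base["L", "MES"] * pi / 180)
  gain_l <- sin(base["L", "LES"] * pi / 180)
  for (delta in c(0.025, 0.05)) {
    m2 <- measure_morphometry(shift(lm, c(0, -delta, 0)))$params  # medial shift
    expect_equal(m2["L", "MJS"], base["L", "MJS"] - delta * gain_m, tolerance = 1e-3)
    expect_equal(m2["L", "LJS"], base["L", "LJS"] + delta * gain_l, tolerance = 1e-3)
    expect_equal(m2["L", "SJS"], base["L", "SJS"], tolerance = 1e-9)
  }
})

test_that("axial condylar angle reports magnitude and pole-order sign", {
  g0 <- condyle_geometry("L", c(0, -9, 0), c(0, 9, 0),
                         circle_outline(c(0, 0), 9, 0), c(0, 0, 7))
  expect_equal(as.numeric(axial_condylar_angle(g0)), 0)
  g45 <- condyle_geometry("L", c(-5, -5, 0), c(5, 5, 0),
                          circle_outline(c(0, 0), 8, 0), c(0, 0, 7))
  a <- axial_condylar_angle(g45)
  expect_equal(as.numeric(a), 45)
  expect_equal(attr(a, "sign"), 1)
})

test_that("eminence steepness covers inclined, flat and vertical walls", {
  mkfossa <- function(theta) {
    t <- seq(-4, 4, 1)
    wall <- cbind(10 + t * cos(theta * pi / 180), 50, -5 + t * sin(theta * pi / 180))
    flat <- cbind(10 + t, 50, -5)
    coronal <- cbind(10, 50 + t * cos(theta * pi / 180), -5 + t * sin(theta * pi / 180))
    fossa_geometry("L", c(10, 50, 0),
                   list(anterior = wall, posterior = flat,
                        medial = coronal, lateral = coronal))
  }
  es <- eminence_steepness(mkfossa(46.49))
  expect_equal(unname(es["AES"]), 46.49, tolerance = 1e-9)
  expect_equal(unname(es["PES"]), 0, tolerance = 1e-9)
  vert <- mkfossa(90)
  expect_error(eminence_steepness(vert), class = "degenerate_geometry")
})

test_that("all TMJ parameters are invariant under world rigid motion", {
  sk <- default_skull(seed = 13, world_pose = FALSE)
  base <- measure_morphometry(sk$landmarks)$params
  set.seed(43)
  for (i in 1:10) {
    moved <- asymjaw:::transform_landmarks(sk$landmarks, random_rigid_tf(60))
    expect_lt(max(abs(as.matrix(measure_morphometry(moved)$params) - as.matrix(base))), 1e-7)
  }
})
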