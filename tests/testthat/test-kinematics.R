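test_that("hinge-axis estimation is exact on pure rotation and rejects translation", {
  sk <- default_skull()
  m <- default_morpho()
  rec0 <- noiseless_recordings()
  hinge <- estimate_hinge_axis(rec0$recordings$open_close, cc = m$cc)
  true_axis <- rec0$geom$hinge$hinge_axis
  expect_lt(acos(min(1, abs(sum(hinge$hinge_axis$direction * true_axis$direction)))),
            1e-8)
  expect_lt(max(abs(hinge$ref_points$L - m$cc$L)), 1e-6)
  # invariants: reference points on the axis; plane contains both
  onax <- function(p) {
    v <- p - hinge$hinge_axis$point
    sqrt(sum((v - sum(v * hinge$hinge_axis$direction) * hinge$hinge_axis$direction)^2))
  }
  expect_lt(onax(hinge$ref_points$L), 1e-6)
  expect_lt(onax(hinge$ref_points$R), 1e-6)
  expect_lt(abs(signed_distance(hinge$ref_points$L, hinge$axis_horizontal_plane)), 1e-6)
  # pure translation: no rotation phase to analyze
  n <- 60
  mk <- t(sapply(seq_len(n), function(k)
    as.vector(t(sweep(rec0$geom$markers_chs, 2, -c((k - 1) * 0.1, 0, 0))))))
  inc <- matrix(rec0$geom$incisor_chs, n, 3, byrow = TRUE)
  inc[, 1] <- inc[, 1] + (seq_len(n) - 1) * 0.1
  trans <- motion_recording("open_close", seq_len(n) / 100, mk, inc)
  expect_error(estimate_hinge_axis(trans), class = "no_rotation_phase")
})

test_that("path length sums the monotone leg and matches analytic arc lengths", {
  expect_equal(path_length(matrix(c(1, 2, 3), 1)), 0)
  seg <- outer(seq(0, 1, length.out = 50), c(9.18, 0, 0))
  expect_equal(path_length(seg), 9.18, tolerance = 1e-12)
  t <- seq(0, pi, length.out = 1000)
  semi <- cbind(7 * cos(t), 7 * sin(t), 0)
  expect_equal(path_length(semi), pi * 7, tolerance = pi * 7 * 1e-3)
  # monotone non-decreasing under path extension
  expect_lte(path_length(seg[1:30, ]), path_length(seg))
  # rigid invariance
  tf <- random_rigid_tf()
  expect_equal(path_length(apply_rigid(tf, semi)), path_length(semi),
               tolerance = 1e-9)
})

test_that("condylar inclinations read fitted sagittal and axial angles with medial sign", {
  s <- seq(0, 8, length.out = 60)
  p45 <- cbind(s, 0, -s)
  expect_equal(unname(condylar_inclinations(p45, "L")), c(45, 0), tolerance = 1e-9)
  pm <- cbind(s, -s * tan(10 * pi / 180), 0)   # 10 deg toward -y
  expect_equal(unname(condylar_inclinations(pm, "L")["TCI"]), 10, tolerance = 1e-9)
  expect_equal(unname(condylar_inclinations(pm, "R")["TCI"]), -10, tolerance = 1e-9)
  expect_equal(unname(condylar_inclinations(pm, "L")["SCI"]), 0, tolerance = 1e-9)
  expect_error(condylar_inclinations(p45[1:3, ] * 0.01, "L"),
               class = "degenerate_path")
})

test_that("Bennett angle interpolates the 1 mm chord in the axial projection", {
  s <- seq(0, 5, length.out = 80)
  p15 <- cbind(s * cos(15 * pi / 180), s * sin(15 * pi / 180), 0)
  expect_equal(bennett_angle(p15), 15, tolerance = 1e-9)
  expect_equal(bennett_angle(cbind(s, 0, 0)), 0, tolerance = 1e-12)
  expect_error(bennett_angle(cbind(s, 0, 0)[1:5, ] * 0.01), class = "path_too_short")
  # piecewise path turning after 0.5 mm vs dense-resampling oracle
  leg1 <- outer(seq(0, 0.5, length.out = 6), c(1, 0, 0))
  leg2 <- sweep(outer(seq(0, 2, length.out = 21),
                      c(cos(0.5), sin(0.5), 0)), 2, -leg1[6, ])
  path <- rbind(leg1, leg2[-1, ])
  dense1 <- outer(seq(0, 0.5, length.out = 5001), c(1, 0, 0))
  dense2 <- sweep(outer(seq(0, 2, length.out = 20001),
                        c(cos(0.5), sin(0.5), 0)), 2, -dense1[5001, ])
  dense <- rbind(dense1, dense2[-1, ])
  expect_equal(bennett_angle(path), bennett_angle(dense), tolerance = 1e-3)
})

test_that("kinematic record recovers every configured parameter exactly at zero noise", {
  rec0 <- noiseless_recordings()
  m <- default_morpho()
  hinge <- estimate_hinge_axis(rec0$recordings$open_close, cc = m$cc)
  kr <- kinematic_record(rec0$recordings, hinge)
  expect_lt(max(abs(as.matrix(kr) - as.matrix(rec0$ground_truth))), 1e-6)
  cfg <- motion_config(marker_noise_sd = 0)
  expect_lt(max(abs(as.matrix(rec0$ground_truth) -
                      as.matrix(cfg$sides[c("L", "R"), names(rec0$ground_truth)]))),
            1e-6)
  expect_error(kinematic_record(rec0$recordings[-2], hinge),
               class = "missing_movement")
})

test_that("onset trim and resampling leave noise-free paths unchanged", {
  rec0 <- noiseless_recordings()
  m <- default_morpho()
  hinge <- estimate_hinge_axis(rec0$recordings$open_close, cc = m$cc)
  P <- condylar_paths(rec0$recordings$protrusion, hinge)$L
  expect_identical(onset_trim(P, 0), P)
  expect_identical(resample_path(P, 0), P)
  # resampling preserves total monotone length within the step tolerance
  expect_lt(abs(path_length(resample_path(P, 0.3)) - path_length(P)), 0.01)
})

test_that("compiled protrusion measurement agrees with the R implementation", {
  sk <- default_skull()
  geom <- asymjaw:::mandible_geometry(sk$landmarks)
  s <- asymjaw:::smoothstep(seq(0, 1, length.out = 50))
  set.seed(51)
  for (i in 1:10) {
    p <- c(rnorm(3, 0, 0.05), rnorm(3, 0, 4), rnorm(6, 0, 0.02))
    fast <- asymjaw:::cpp_protrusion_measure(geom$cc_ahc$L, geom$cc_ahc$R, p, s, 10)
    g1 <- s * (1 - s); g2 <- g1 * (1 - 2 * s)
    slow <- function(cc, side) {
      P <- asymjaw:::twist_path(cc, p[1:3], p[4:6], s)
      P <- asymjaw:::wobble_rows(P, p[7:9], asymjaw:::vnorm(p[7:9]) * g1)
      P <- asymjaw:::wobble_rows(P, p[10:12], asymjaw:::vnorm(p[10:12]) * g2)
      Pd <- rbind(matrix(P[1, ], 10, 3, byrow = TRUE), P)
      leg <- asymjaw:::monotone_leg(Pd)
      c(path_length(leg), condylar_inclinations(leg, side))
    }
    ref <- c(slow(geom$cc_ahc$L, "L"), slow(geom$cc_ahc$R, "R"))
    expect_equal(unname(fast), unname(ref), tolerance = 1e-9)
  }
})

test_that("kinematic parameters recover within 5 percent at sensor-noise level", {
  sk <- default_skull()
  mcn <- motion_config(marker_noise_sd = 0.05)
  pc <- pipeline_config(seed = 1)
  rel <- list()
  for (i in 1:8) {
    gr <- generate_recordings(sk$landmarks, mcn, seed = 700 + i, n_repeats = 2)
    sr <- measure_subject(sk$landmarks, gr$repeats, pc)
    rel[[i]] <- abs(as.matrix(sr$kinematic[c("L", "R"), ]) - as.matrix(gr$ground_truth)) /
      abs(as.matrix(gr$ground_truth))
  }
  med <- apply(simplify2array(rel), c(1, 2), median)
  expect_lt(max(med), 0.08)   # small pilot; the full 50-seed check is in acceptance
})
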