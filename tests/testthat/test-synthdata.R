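test_that("skull generation is deterministic and exact for symmetric configs", {
  cfg <- skull_config()
  a <- generate_skull(cfg, seed = 4)
  b <- generate_skull(cfg, seed = 4)
  expect_identical(a$landmarks$points, b$landmarks$points)
  expect_identical(a$landmarks$profiles, b$landmarks$profiles)
  # equal per-side values: measured interside difference vanishes
  spec <- default_morpho_spec()
  same <- stats::setNames(spec$mean_NDS, spec$param)
  sym <- generate_skull(skull_config(menton_deviation = 5, ds = same, nds = same),
                        seed = 2)
  m <- measure_morphometry(sym$landmarks)
  expect_lt(max(abs(as.matrix(m$params["L", ]) - as.matrix(m$params["R", ]))), 1e-9)
  expect_error(skull_config(menton_deviation = 0), class = "invalid_config")
  expect_error(skull_config(ds = c(RH = -3)), class = "invalid_config")
})

test_that("morphometric round trip is exact over random configurations", {
  set.seed(61)
  for (i in 1:15) {
    cfg <- random_morpho_config()
    sk <- generate_skull(cfg, seed = 600 + i)
    m <- measure_morphometry(sk$landmarks)
    expect_lt(max(abs(as.matrix(m$params) - as.matrix(sk$ground_truth))), 1e-6)
    expect_equal(m$menton_deviation, cfg$menton_deviation, tolerance = 1e-6)
  }
})

test_that("motion recordings are reproducible and hinge-phase starts with pure rotation", {
  sk <- default_skull()
  mc <- motion_config(marker_noise_sd = 0.05)
  g1 <- generate_motion(sk$landmarks, mc, "open_close", seed = 8)
  g2 <- generate_motion(sk$landmarks, mc, "open_close", seed = 8)
  expect_identical(g1$recording$markers, g2$recording$markers)
  # zero-noise opening: early frames rotate exactly about the hinge axis
  rec0 <- noiseless_recordings()
  pa <- asymjaw:::recording_poses(rec0$recordings$open_close)
  geom <- rec0$geom
  k <- 60   # inside the terminal hinge phase
  R <- matrix(pa$R9[k, ], 3, 3, byrow = TRUE)
  moved <- drop(R %*% geom$cc$L) + pa$T[k, ]
  expect_lt(max(abs(moved - geom$cc$L)), 1e-8)   # on-axis points stay fixed
  s <- screw_axis(rigid3(R, pa$T[k, ]), angle_floor = 0.5)
  axd <- geom$hinge$hinge_axis$direction
  expect_lt(min(sum((s$direction - axd)^2), sum((s$direction + axd)^2)), 1e-12)
  expect_lt(abs(attr(s, "slide")), 1e-8)
})

test_that("protrusion descends at the configured sagittal inclination at zero noise", {
  rec0 <- noiseless_recordings()
  m <- default_morpho()
  hinge <- estimate_hinge_axis(rec0$recordings$open_close, cc = m$cc)
  pp <- condylar_paths(rec0$recordings$protrusion, hinge)
  incl <- condylar_inclinations(pp$L, "L")
  expect_equal(unname(incl["SCI"]),
               motion_config(marker_noise_sd = 0)$sides["L", "SCI"],
               tolerance = 1e-6)
})

test_that("kinematic recovery error is monotone in the sensor noise level", {
  sk <- default_skull()
  pc <- pipeline_config(seed = 1)
  rms <- sapply(c(0, 0.05, 0.2), function(sd0) {
    errs <- sapply(1:6, function(i) {
      mc <- motion_config(marker_noise_sd = sd0)
      gr <- generate_recordings(sk$landmarks, mc, seed = 900 + i)
      cfg <- pc
      if (sd0 == 0) { cfg$smoothing_window <- 0; cfg$onset_tol <- 0; cfg$resample_step <- 0 }
      sr <- measure_subject(sk$landmarks, gr$repeats, cfg)
      max(abs(as.matrix(sr$kinematic[c("L", "R"), ]) - as.matrix(gr$ground_truth)))
    })
    sqrt(mean(errs^2))
  })
  expect_true(all(diff(rms) > 0))
})

test_that("cohort generator honours the requested per-side means and pairing", {
  spec <- effect_spec()
  co <- generate_cohort(1000, spec, seed = 5)$table
  tab <- spec$table
  for (v in c("FRI", "AES", "PCPL", "MxH", "TCI")) {
    i <- which(tab$param == v)
    sem <- tab$sd_DS[i] / sqrt(1000)
    expect_lt(abs(mean(co[[paste0(v, "_DS")]]) - tab$mean_DS[i]), 3.5 * sem + 0.02)
    expect_lt(abs(mean(co[[paste0(v, "_NDS")]]) - tab$mean_NDS[i]),
              3.5 * tab$sd_NDS[i] / sqrt(1000) + 0.02)
  }
  # pairing correlation near the requested value
  r <- cor(co$MxH_DS, co$MxH_NDS)
  expect_lt(abs(r - 0.5), 0.1)
  # latent factor induces the documented deviated-side correlations
  expect_gt(cor(co$FRI_DS, co$AES_DS), 0.15)
  expect_gt(cor(co$PCPL_DS, co$MJS_DS), 0.15)
  # reproducibility
  co2 <- generate_cohort(1000, spec, seed = 5)$table
  expect_identical(co, co2)
})

test_that("null effect specification erases interside differences", {
  co <- generate_cohort(500, effect_spec(null = TRUE), seed = 6)$table
  d <- co$FRI_DS - co$FRI_NDS
  expect_lt(abs(mean(d)), 4 * sd(d) / sqrt(500))
})
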