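# Synthetic jaw-motion generator. Border movements are rigid-body motions
# constructed in axis-horizontal coordinates (AHC: hinge axis = y-axis,
# axis-horizontal plane = z = 0, +x anterior):
#   open_close    - terminal hinge rotation (pure rotation about the axis for
#                   the first hinge_phase_deg) followed by an eminence glide
#                   (translation along a descending direction + yaw), the
#                   glide solved so per-side condylar path lengths equal the
#                   configured OCPL; includes the closing return leg.
#   protrusion    - constant-twist (screw) motion whose six twist parameters
#                   are solved so the measured per-side PCPL/SCI/TCI on the
#                   noiseless sampled paths equal the configured values.
#   laterotrusion - helical yaw about a vertical axis + descent; the axis is
#                   placed on the Apollonius circle fixing the non-working
#                   condyle/incisor radius ratio (NCPL vs NIPL) and its
#                   bearing solved for the Bennett angle.
# Marker noise is isotropic i.i.d. Gaussian, added to every coordinate of the
# four mandibular markers and the tracked incisor.

#' Default per-side dynamic-parameter values
#'
#' Deviated- / non-deviated-side means and SDs of the seven dynamic
#' parameters used as generator defaults and cohort effect specification.
#'
#' @return data frame with columns `param`, `mean_DS`, `sd_DS`, `mean_NDS`,
#'   `sd_NDS`.
#' @export
default_kinematic_spec <- function() {
  data.frame(
    param    = KINEMATIC_PARAMS,
    mean_DS  = c(15.27, 9.18, 44.39, 4.20, 14.39, 8.15, 6.59),
    sd_DS    = c(2.75, 1.73, 5.21, 2.86, 3.99, 1.46, 1.18),
    mean_NDS = c(14.21, 6.88, 39.57, -2.44, 9.11, 6.12, 5.81),
    sd_NDS   = c(3.60, 1.64, 7.48, 2.23, 2.35, 1.70, 1.03))
}

#' Motion configuration
#'
#' @param deviated_side `"left"` or `"right"`; deviated-side targets are
#'   assigned to this side.
#' @param ds,nds named numeric vectors overriding the per-side defaults of
#'   [default_kinematic_spec()] (`OCPL`, `PCPL`, `SCI`, `TCI`, `BA`, `NCPL`,
#'   `NIPL`).
#' @param marker_noise_sd isotropic sensor noise SD per coordinate (mm).
#' @param frame_rate sampling rate (Hz).
#' @param dwell_s initial intercuspal rest before motion (s).
#' @param open_s,protrusion_s,laterotrusion_s durations of the moving leg (s).
#' @param hinge_phase_deg pure-rotation (terminal hinge) opening phase
#'   (degrees of opening rotation).
#' @param max_opening_deg total opening rotation (degrees).
#' @param glide_angle_deg sagittal descent angle of the opening glide
#'   direction against the axis-horizontal plane.
#' @return object of class `motion_config` with per-side targets in `sides`
#'   (rows `L`, `R`).
#' @export
motion_config <- function(deviated_side = "left", ds = NULL, nds = NULL,
                          marker_noise_sd = 0.05, frame_rate = 100,
                          dwell_s = 0.4, open_s = 1.6, protrusion_s = 2.0,
                          laterotrusion_s = 2.4, hinge_phase_deg = 10,
                          max_opening_deg = 30, glide_angle_deg = 50) {
  spec <- default_kinematic_spec()
  dsv <- stats::setNames(spec$mean_DS, spec$param)
  ndv <- stats::setNames(spec$mean_NDS, spec$param)
  if (!is.null(ds)) dsv[names(ds)] <- ds
  if (!is.null(nds)) ndv[names(nds)] <- nds
  if (marker_noise_sd < 0 || frame_rate <= 0)
    aj_stop("invalid_config", "noise sd must be >= 0 and frame rate > 0")
  if (any(c(dsv[c("OCPL", "PCPL", "NCPL", "NIPL")],
            ndv[c("OCPL", "PCPL", "NCPL", "NIPL")]) <= 0))
    aj_stop("invalid_config", "path-length targets must be positive")
  sides <- if (deviated_side == "left") rbind(L = dsv, R = ndv) else rbind(L = ndv, R = dsv)
  structure(list(sides = as.data.frame(sides), deviated_side = deviated_side,
                 marker_noise_sd = marker_noise_sd, frame_rate = frame_rate,
                 dwell_s = dwell_s, open_s = open_s,
                 protrusion_s = protrusion_s, laterotrusion_s = laterotrusion_s,
                 hinge_phase_deg = hinge_phase_deg,
                 max_opening_deg = max_opening_deg,
                 glide_angle_deg = glide_angle_deg),
            class = "motion_config")
}

smoothstep <- function(t) 3 * t^2 - 2 * t^3

# mandibular rigid-body geometry of a subject: condylar centres, the true
# hinge frame (axis through the centres), marker array and incisor, all
# re-expressed in AHC for motion construction
mandible_geometry <- function(landmarks) {
  frame <- build_head_frame(landmarks)
  lm <- to_chs(landmarks, frame)
  ccL <- condyle_center(condyle_from_landmarks(lm, "_L"))
  ccR <- condyle_center(condyle_from_landmarks(lm, "_R"))
  hinge <- hinge_frame(line3(ccR, ccL - ccR), cc = list(L = ccL, R = ccR))
  dev <- get_landmark(lm, "Me")[2]
  # para-occlusal face-bow transmitter array with genuine 3D extent (a nearly
  # planar array leaves the pitch axis ill-constrained and the pose noise is
  # amplified over the ~110 mm lever to the condyles)
  markers_chs <- rbind(c(60, -62, -45), c(60, 62, -45),
                       c(112, 0, -33), c(95, 0, -72))
  incisor_chs <- c(90, 0.5 * dev, -48)
  list(frame = frame, cc = list(L = ccL, R = ccR), hinge = hinge,
       markers_chs = markers_chs, incisor_chs = incisor_chs,
       cc_ahc = list(L = apply_rigid(hinge$to_ahc, ccL),
                     R = apply_rigid(hinge$to_ahc, ccR)),
       incisor_ahc = apply_rigid(hinge$to_ahc, incisor_chs))
}

# conjugate an AHC pose into head coordinates
ahc_pose_to_chs <- function(pose_ahc, hinge) {
  compose_rigid(invert_rigid(hinge$to_ahc), compose_rigid(pose_ahc, hinge$to_ahc))
}

# ---- closed-form AHC path evaluators ---------------------------------------

# yaw about the vertical axis through axial point a2 by psi (rad, vector over
# frames) with vertical drop dz (vector), applied to AHC point p
yaw_path <- function(p, a2, psi, dz) {
  r <- p[1:2] - a2
  cbind(a2[1] + cos(psi) * r[1] - sin(psi) * r[2],
        a2[2] + sin(psi) * r[1] + cos(psi) * r[2],
        p[3] - dz)
}

# constant-twist path: pose(s) = exp(s * (w, v)) applied to p (all AHC)
twist_path <- function(p, w, v, s) {
  th <- vnorm(w)
  if (th < 1e-12)
    return(cbind(p[1] + s * v[1], p[2] + s * v[2], p[3] + s * v[3]))
  u <- w / th
  up <- cross3(u, p); upp <- cross3(u, up)
  uv <- cross3(u, v); uvv <- cross3(u, uv)
  sn <- sin(th * s); cs1 <- 1 - cos(th * s)
  base <- matrix(p, length(s), 3, byrow = TRUE)
  base + outer(sn, up) + outer(cs1, upp) +
    outer(s, v) + outer(cs1 / th, uv) + outer(th * s - sn, uvv) / th
}

# damped quasi-Newton with numeric Jacobian and Broyden rank-1 updates
# (fresh finite-difference Jacobian on stalls or every few iterations);
# returns the best parameters found
newton_solve <- function(f, x0, tol = 1e-9, max_iter = 60, fd_eps = 1e-6,
                         refresh_every = 1) {
  x <- x0; fx <- f(x)
  best <- list(x = x, f = fx, norm = max(abs(fx)))
  fd_jac <- function(x, fx) {
    J <- matrix(0, length(fx), length(x))
    for (j in seq_along(x)) {
      xp <- x; xp[j] <- xp[j] + fd_eps
      J[, j] <- (f(xp) - fx) / fd_eps
    }
    J
  }
  J <- NULL; since_fd <- 0L
  for (it in seq_len(max_iter)) {
    if (max(abs(fx)) < tol) break
    if (is.null(J) || since_fd >= refresh_every) { J <- fd_jac(x, fx); since_fd <- 0L }
    step <- tryCatch(solve(J, fx), error = function(e) {
      sv <- svd(J)
      dinv <- ifelse(sv$d > 1e-10 * max(sv$d), 1 / sv$d, 0)
      drop(sv$v %*% (dinv * crossprod(sv$u, fx)))
    })
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      fn <- tryCatch(f(xn), error = function(e) NULL)
      if (!is.null(fn) && max(abs(fn)) < max(abs(fx))) break
      lambda <- lambda / 2
      if (lambda < 1e-4) { xn <- x; fn <- fx; break }
    }
    if (lambda < 1e-4) {
      # stalled on the approximate Jacobian: force a fresh one, then give up
      if (since_fd == 0L) break
      J <- NULL
      next
    }
    dx <- xn - x; df <- fn - fx
    J <- J + ((df - drop(J %*% dx)) %o% dx) / sum(dx * dx)
    since_fd <- since_fd + 1L
    x <- xn; fx <- fn
    if (max(abs(fx)) < best$norm) best <- list(x = x, f = fx, norm = max(abs(fx)))
  }
  best
}

# ---- movement solvers ------------------------------------------------------

solve_open_close <- function(geom, cfg, n_open) {
  qh <- cfg$hinge_phase_deg / cfg$max_opening_deg
  q <- smoothstep(seq(0, 1, length.out = n_open))
  s <- pmax(0, (q - qh) / (1 - qh))
  alpha <- rad(cfg$glide_angle_deg)
  d_gl <- c(cos(alpha), 0, -sin(alpha))
  ccL <- geom$cc_ahc$L; ccR <- geom$cc_ahc$R
  paths <- function(p) {
    psi <- rad(s * p[2])
    list(L = yaw_path(ccL, c(0, 0), psi, 0) + outer(s * p[1], d_gl),
         R = yaw_path(ccR, c(0, 0), psi, 0) + outer(s * p[1], d_gl))
  }
  tgt <- c(cfg$sides["L", "OCPL"], cfg$sides["R", "OCPL"])
  f <- function(p) {
    pp <- paths(p)
    c(path_length(pp$L) - tgt[1], path_length(pp$R) - tgt[2])
  }
  sol <- newton_solve(f, c(mean(tgt), 0))
  # opening sense about the +y hinge axis: incisor must move inferiorly
  inc_rot <- apply_rigid(screw_transform(c(0, 0, 0), c(0, 1, 0), 5), geom$incisor_ahc)
  rot_sign <- if (inc_rot[3] - geom$incisor_ahc[3] < 0) +1 else -1
  pose_ahc <- lapply(seq_along(q), function(k) {
    hingepose <- screw_transform(c(0, 0, 0), c(0, 1, 0),
                                 rot_sign * q[k] * cfg$max_opening_deg)
    glide <- compose_rigid(rigid3(diag(3), s[k] * sol$x[1] * d_gl),
                           screw_transform(c(0, 0, 0), c(0, 0, 1), s[k] * sol$x[2]))
    compose_rigid(glide, hingepose)
  })
  pp <- paths(sol$x)
  gt <- c(OCPL_L = path_length(pp$L), OCPL_R = path_length(pp$R))
  list(pose_ahc = pose_ahc, ground_truth = gt, residual = sol$norm)
}

# rotate rows of path matrix P about unit axis by per-row angles a (rad)
wobble_rows <- function(P, m, a) {
  th <- vnorm(m)
  if (th < 1e-12) return(P)
  u <- m / th
  ca <- cos(a); sa <- sin(a)
  ux <- cbind(u[2] * P[, 3] - u[3] * P[, 2],
              u[3] * P[, 1] - u[1] * P[, 3],
              u[1] * P[, 2] - u[2] * P[, 1])
  ud <- drop(P %*% u)
  P * ca + ux * sa + outer((1 - ca) * ud, u)
}

solve_protrusion <- function(geom, cfg, n_frames, n_dwell = 0) {
  s <- smoothstep(seq(0, 1, length.out = n_frames))
  ccL <- geom$cc_ahc$L; ccR <- geom$cc_ahc$R
  # constant twist (6 params) + even and odd mid-course wobble rotations
  # vanishing at both endpoints: exp(g2(s)[m2]) o exp(g1(s)[m1]) o exp(s(w,v))
  # with g1 = s(1-s) (bows the path) and g2 = s(1-s)(1-2s) (skews it, which
  # rotates fitted inclinations relative to endpoint chords - slack the rigid
  # intercondylar constraint alone cannot provide)
  g1 <- s * (1 - s); g2 <- s * (1 - s) * (1 - 2 * s)
  n <- length(s); i1 <- seq_len(n); i2 <- n + i1
  paths <- function(p) {
    P <- rbind(twist_path(ccL, p[1:3], p[4:6], s),
               twist_path(ccR, p[1:3], p[4:6], s))
    P <- wobble_rows(P, p[7:9], vnorm(p[7:9]) * c(g1, g1))
    P <- wobble_rows(P, p[10:12], vnorm(p[10:12]) * c(g2, g2))
    list(L = P[i1, , drop = FALSE], R = P[i2, , drop = FALSE])
  }
  # measured-consistent fit: truncate at the monotone leg, and weight the
  # first point by n_dwell + 1 (the dwell frames sit on the path start)
  wfit <- function(P, side) {
    sigma <- if (side == "L") +1 else -1
    d1 <- P[, 1] - P[1, 1]; d2 <- P[, 2] - P[1, 2]; d3 <- P[, 3] - P[1, 3]
    kmax <- which.max(d1 * d1 + d2 * d2 + d3 * d3)
    P <- P[seq_len(kmax), , drop = FALSE]
    w <- c(n_dwell + 1, rep(1, nrow(P) - 1))
    wtls <- function(h, v) {
      sw <- sum(w); mh <- sum(w * h) / sw; mv <- sum(w * v) / sw
      a <- sum(w * (h - mh)^2); cc2 <- sum(w * (v - mv)^2)
      b <- sum(w * (h - mh) * (v - mv))
      ang <- 0.5 * atan2(2 * b, a - cc2)
      c(cos(ang), sin(ang))
    }
    dsag <- wtls(P[, 1], P[, 3])
    dax <- wtls(P[, 1], P[, 2])
    if (dax[1] < 0) dax <- -dax
    c(deg(atan2(abs(dsag[2]), abs(dsag[1]))), deg(atan2(-sigma * dax[2], dax[1])))
  }
  measure <- function(pp) {
    c(path_length(pp$L), wfit(pp$L, "L"), path_length(pp$R), wfit(pp$R, "R"))
  }
  tgt <- c(as.numeric(cfg$sides["L", c("PCPL", "SCI", "TCI")]),
           as.numeric(cfg$sides["R", c("PCPL", "SCI", "TCI")]))
  tgt <- unname(tgt)
  # rigid-body feasibility of the transverse inclinations: both condyles are
  # carried by one mandible, so their transverse drifts can differ only by
  # the second-order intercondylar slack (~0.3 mm over a protrusive leg).
  # Target pairs outside that band are projected onto a common drift (the
  # realized values are returned as ground truth).
  xl <- tgt[1] * cos(rad(tgt[2])); xr <- tgt[4] * cos(rad(tgt[5]))
  dyl <- -tan(rad(tgt[3])) * xl; dyr <- tan(rad(tgt[6])) * xr
  project_common <- function(tg) {
    mid <- (dyl + dyr) / 2
    tg[3] <- deg(atan2(-mid, xl))
    tg[6] <- deg(atan2(mid, xr))
    tg
  }
  attempt <- function(tg) {
    f <- function(p) cpp_protrusion_measure(ccL, ccR, p, s, n_dwell) - tg
    dira <- function(pcpl, sci, tci, sigma) {
      u <- c(1, -sigma * tan(rad(tci)), -tan(rad(sci)))
      u / vnorm(u) * pcpl
    }
    dL <- dira(tg[1], tg[2], tg[3], +1)
    dR <- dira(tg[4], tg[5], tg[6], -1)
    delta0 <- ccL - ccR
    w0 <- cross3(delta0, dL - dR) / sum(delta0^2)
    newton_solve(f, c(w0, (dL + dR) / 2, rep(0, 6)), tol = 1e-9, max_iter = 40)
  }
  if (abs(dyl - dyr) <= 0.28) {
    sol <- attempt(tgt)
    if (sol$norm > 1e-8) sol <- attempt(project_common(tgt))
  } else {
    sol <- attempt(project_common(tgt))
  }
  m1 <- sol$x[7:9]; m2 <- sol$x[10:12]
  wob <- function(m, g) {
    if (vnorm(m) < 1e-12) diag(3) else rotation_about_axis(m, deg(vnorm(m) * g))
  }
  pose_ahc <- lapply(seq_along(s), function(k) {
    tw <- twist_pose(sol$x[1:3], sol$x[4:6], s[k])
    R12 <- wob(m2, g2[k]) %*% wob(m1, g1[k])
    compose_rigid(rigid3(R12), tw)
  })
  pp <- paths(sol$x)
  m <- measure(pp)
  gt <- stats::setNames(m, c("PCPL_L", "SCI_L", "TCI_L", "PCPL_R", "SCI_R", "TCI_R"))
  list(pose_ahc = pose_ahc, ground_truth = gt, residual = sol$norm)
}

solve_laterotrusion <- function(geom, cfg, working, n_frames) {
  nw <- if (working == "left") "R" else "L"
  tgt <- stats::setNames(as.numeric(cfg$sides[nw, c("NCPL", "NIPL", "BA")]),
                         c("NCPL", "NIPL", "BA"))
  C2 <- geom$cc_ahc[[nw]][1:2]
  I2 <- geom$incisor_ahc[1:2]
  u <- smoothstep(seq(0, 1, length.out = n_frames))
  # descent fixes the incisor/condyle radius ratio k (Apollonius circle);
  # k also bounds the reachable axis bearings (half-width asin(k) around the
  # condyle-to-incisor direction), so pick the descent adaptively: as steep
  # as 45 degrees but flat enough that the Bennett-angle bearing is reachable
  kmax <- min(1.5, tgt["NIPL"] / tgt["NCPL"])
  phic0 <- atan2(I2[2] - C2[2], I2[1] - C2[1])
  k_req <- if (kmax >= 1) 0 else {
    spans <- c()
    for (thet in c(tgt["BA"], -tgt["BA"], 180 - tgt["BA"], tgt["BA"] - 180))
      for (off in c(90, -90)) {
        phi <- rad(thet + off)
        spans <- c(spans, abs(atan2(sin(phi - phic0), cos(phi - phic0))))
      }
    sin(min(pi / 2 * 0.999, min(spans) * 1.03))
  }
  d45 <- tgt["NCPL"] * sin(rad(45))
  k45 <- sqrt(abs(tgt["NIPL"]^2 - d45^2) / abs(tgt["NCPL"]^2 - d45^2))
  k <- if (kmax >= 1) k45 else min(max(k45, k_req), 0.985 * kmax)
  if (abs(1 - k) < 1e-6) k <- k - 1e-5
  d2k <- (tgt["NIPL"]^2 - k^2 * tgt["NCPL"]^2) / (1 - k^2)
  d_tot0 <- sqrt(max(0.01, d2k))
  ctr <- (I2 - k^2 * C2) / (1 - k^2)
  Dv <- ctr - C2; D <- vnorm(Dv)
  Rap <- k * vnorm(I2 - C2) / abs(1 - k^2)
  phic <- atan2(Dv[2], Dv[1])
  # axis position for a radius bearing phi: intersection of the ray from the
  # non-working condyle with the Apollonius circle (farther branch)
  axis_at <- function(phi) {
    e <- c(cos(phi), sin(phi))
    b <- sum(e * Dv)
    disc <- b^2 - (D^2 - Rap^2)
    if (disc < 0) return(NULL)
    t <- b + sqrt(disc)
    if (t <= 1) return(NULL)
    C2 + t * e
  }
  eval_phi <- function(phi, warm = NULL) {
    a2 <- axis_at(phi)
    if (is.null(a2)) return(NULL)
    r <- C2 - a2
    tang <- c(-r[2], r[1]); sense <- if (tang[1] >= 0) +1 else -1
    r_nw <- vnorm(r)
    psi0 <- sense * sqrt(max(1e-10, (tgt["NCPL"]^2 - tgt["NIPL"]^2) /
                               (r_nw^2 - vnorm(I2 - a2)^2)))
    if (!is.finite(psi0)) return(NULL)
    pnw <- function(p) yaw_path(geom$cc_ahc[[nw]], a2, u * p[1], u * p[2])
    pinc <- function(p) yaw_path(geom$incisor_ahc, a2, u * p[1], u * p[2])
    f2 <- function(p) c(path_length(pnw(p)) - tgt["NCPL"],
                        path_length(pinc(p)) - tgt["NIPL"])
    x0 <- if (!is.null(warm)) warm else c(psi0, unname(d_tot0))
    sol <- newton_solve(f2, x0, tol = 1e-10, max_iter = 30)
    if (sol$norm > 1e-8) return(NULL)
    Pnw <- pnw(sol$x)
    list(ba = bennett_angle(monotone_leg(Pnw)), p = sol$x, a2 = a2, Pnw = Pnw)
  }
  span <- if (Rap / D < 1) asin(min(1, Rap / D)) * 0.999 else pi * 0.999
  # bearing candidates that approximately realize the target tangent angle
  cands <- c()
  for (thet in c(tgt["BA"], -tgt["BA"], 180 - tgt["BA"], tgt["BA"] - 180)) {
    for (off in c(90, -90)) {
      phi <- rad(thet + off)
      dphi <- atan2(sin(phi - phic), cos(phi - phic))
      if (abs(dphi) <= span) cands <- c(cands, phic + dphi)
    }
  }
  cands <- unique(c(cands, phic + seq(-span, span, length.out = 17)))
  best <- NULL; bestphi <- NA; bestg <- Inf
  for (phi in cands) {
    ev <- eval_phi(phi)
    if (is.null(ev)) next
    g <- ev$ba - tgt["BA"]
    if (abs(g) < abs(bestg)) { best <- ev; bestphi <- phi; bestg <- g }
  }
  if (is.null(best))
    aj_stop("invalid_config", "laterotrusion targets not rigid-body feasible")
  # secant refinement on the bearing
  phi1 <- bestphi; g1 <- bestg
  phi2 <- phi1 + 0.01 * if (g1 > 0) -1 else 1
  for (it in 1:30) {
    if (abs(g1) < 1e-9) break
    ev2 <- eval_phi(phi2, warm = best$p)
    if (is.null(ev2)) { phi2 <- (phi1 + phi2) / 2; next }
    g2 <- ev2$ba - tgt["BA"]
    if (abs(g2) < abs(g1)) { best <- ev2 }
    if (abs(g2 - g1) < 1e-14) break
    phin <- phi2 - g2 * (phi2 - phi1) / (g2 - g1)
    dphin <- atan2(sin(phin - phic), cos(phin - phic))
    phin <- phic + max(-span, min(span, dphin))
    phi1 <- phi2; g1 <- g2; phi2 <- phin
  }
  a2 <- best$a2; p <- best$p
  pose_ahc <- lapply(seq_along(u), function(kk) {
    compose_rigid(rigid3(diag(3), c(0, 0, -u[kk] * p[2])),
                  screw_transform(c(a2, 0), c(0, 0, 1), deg(u[kk] * p[1])))
  })
  Pinc <- yaw_path(geom$incisor_ahc, a2, u * p[1], u * p[2])
  gt <- stats::setNames(
    c(path_length(best$Pnw), bennett_angle(monotone_leg(best$Pnw)), path_length(Pinc)),
    paste0(c("NCPL_", "BA_", "NIPL_"), nw))
  list(pose_ahc = pose_ahc, ground_truth = gt, residual = abs(best$ba - tgt["BA"]))
}

#' Generate one synthetic motion recording
#'
#' Builds the rigid-body border movement whose measured dynamic parameters at
#' zero noise equal the configured values (up to solver tolerance ~1e-9
#' whenever the targets are rigid-body feasible; otherwise the closest
#' feasible motion, with the realized values reported as ground truth),
#' samples the marker and incisor trajectories in head-referenced
#' coordinates, and adds i.i.d. isotropic Gaussian sensor noise. Open-close
#' begins with a pure rotation about the hinge axis (terminal hinge phase)
#' before translation starts and includes the closing return leg.
#'
#' @param landmarks subject `landmark_set` (world coordinates), or the
#'   internal geometry from [generate_recordings()].
#' @param mconfig `motion_config`.
#' @param movement one of `"open_close"`, `"protrusion"`,
#'   `"laterotrusion_left"`, `"laterotrusion_right"`.
#' @param seed integer seed (sensor noise).
#' @return list with `recording` (`motion_recording`), `ground_truth` (named
#'   vector of realized noiseless parameters) and `solver_residual`.
#' @export
generate_motion <- function(landmarks, mconfig, movement, seed = 1L) {
  geom <- if (inherits(landmarks, "landmark_set")) mandible_geometry(landmarks) else landmarks
  plan <- plan_motion(geom, mconfig, movement)
  list(recording = emit_recording(plan, geom, mconfig, seed),
       ground_truth = plan$ground_truth, solver_residual = plan$residual)
}

# solve a movement once: noiseless marker/incisor trajectories + ground truth
plan_motion <- function(geom, mconfig, movement) {
  fr <- mconfig$frame_rate
  n_dwell <- max(10, round(mconfig$dwell_s * fr))
  sol <- switch(movement,
    open_close = solve_open_close(geom, mconfig, max(20, round(mconfig$open_s * fr))),
    protrusion = solve_protrusion(geom, mconfig,
                                  max(20, round(mconfig$protrusion_s * fr)), n_dwell),
    laterotrusion_left = solve_laterotrusion(geom, mconfig, "left",
                                             max(20, round(mconfig$laterotrusion_s * fr))),
    laterotrusion_right = solve_laterotrusion(geom, mconfig, "right",
                                              max(20, round(mconfig$laterotrusion_s * fr))),
    aj_stop("invalid_config", sprintf("unknown movement '%s'", movement)))
  poses <- lapply(sol$pose_ahc, ahc_pose_to_chs, hinge = geom$hinge)
  if (movement == "open_close") poses <- c(poses, rev(poses)[-1])
  poses <- c(rep(list(rigid3()), n_dwell), poses)
  mk <- t(vapply(poses, function(tf) as.vector(t(apply_rigid(tf, geom$markers_chs))),
                 numeric(12)))
  inc <- t(vapply(poses, function(tf) apply_rigid(tf, geom$incisor_chs), numeric(3)))
  list(movement = movement, markers = mk, incisor = inc,
       ground_truth = sol$ground_truth, residual = sol$residual)
}

# sample one noisy recording from a solved movement plan
emit_recording <- function(plan, geom, mconfig, seed) {
  mk <- plan$markers; inc <- plan$incisor
  set.seed(as.integer(seed))
  if (mconfig$marker_noise_sd > 0) {
    mk <- mk + stats::rnorm(length(mk), 0, mconfig$marker_noise_sd)
    inc <- inc + stats::rnorm(length(inc), 0, mconfig$marker_noise_sd)
  }
  motion_recording(plan$movement, seq_len(nrow(mk)) / mconfig$frame_rate, mk, inc)
}

#' Generate all four border-movement recordings for a subject
#'
#' @param landmarks subject `landmark_set`.
#' @param mconfig `motion_config`.
#' @param seed integer seed; sub-seeds are derived per movement and repeat.
#' @param n_repeats number of repeated acquisitions (independent sensor
#'   noise on the same movements); parameter estimates are averaged over
#'   repeats downstream, mirroring the duplicate-recording protocol.
#' @return list with `recordings` (first repeat: named list of four
#'   `motion_recording`s), `repeats` (list of such lists), `ground_truth`
#'   (data frame, rows `L`/`R`, the seven dynamic parameters) and `geom`
#'   (internal mandible geometry).
#' @export
generate_recordings <- function(landmarks, mconfig, seed = 1L, n_repeats = 1L) {
  geom <- mandible_geometry(landmarks)
  movements <- c("open_close", "protrusion", "laterotrusion_left", "laterotrusion_right")
  gt <- data.frame(row.names = c("L", "R"))
  plans <- list()
  for (i in seq_along(movements)) {
    plans[[movements[i]]] <- plan_motion(geom, mconfig, movements[i])
    g <- plans[[movements[i]]]$ground_truth
    for (nm in names(g)) {
      pr <- sub("_[LR]$", "", nm); sd <- sub("^.*_", "", nm)
      gt[sd, pr] <- g[[nm]]
    }
  }
  repeats <- lapply(seq_len(n_repeats), function(r) {
    stats::setNames(lapply(seq_along(movements), function(i)
      emit_recording(plans[[i]], geom, mconfig,
                     (as.integer(seed) %% 100000000L) * 13L + 4L * (r - 1L) + i)),
      movements)
  })
  list(recordings = repeats[[1]], repeats = repeats,
       ground_truth = gt[, KINEMATIC_PARAMS], geom = geom)
}
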