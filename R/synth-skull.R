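# Synthetic skull generator: a stylized landmark/polyline model of an
# asymmetric skull, constructed directly in canonical head coordinates so
# that applying the measurement modules at zero noise returns the configured
# parameter values exactly, then (optionally) moved by a random rigid world
# pose. Measurements depend only on landmarks and wall profiles, so no
# anatomical mesh is needed.

MORPHO_PARAMS <- c("MxH", "RH", "FRI", "LRI", "BL",
                   "APCP", "TCP", "VCP",
                   "SJS", "AJS", "PJS", "MJS", "LJS", "ACA",
                   "AES", "PES", "MES", "LES")

KINEMATIC_PARAMS <- c("OCPL", "PCPL", "SCI", "TCI", "BA", "NCPL", "NIPL")

#' Default per-side morphometric values
#'
#' Deviated-side and non-deviated-side means and SDs of the 18 per-side
#' morphometric parameters used as generator defaults and as the cohort
#' effect specification.
#'
#' @return data frame with columns `param`, `mean_DS`, `sd_DS`, `mean_NDS`,
#'   `sd_NDS`.
#' @export
default_morpho_spec <- function() {
  data.frame(
    param    = MORPHO_PARAMS,
    mean_DS  = c(49.67, 45.91, 82.34, 86.41, 74.62,
                 13.21, 52.03, 8.72,
                 2.05, 2.13, 1.59, 2.65, 1.48, 21.18,
                 46.49, 58.30, 48.72, 37.77),
    sd_DS    = c(3.56, 5.39, 3.70, 6.84, 5.05,
                 3.33, 2.51, 3.07,
                 0.71, 0.71, 0.46, 0.69, 0.59, 6.37,
                 9.21, 9.03, 12.17, 7.97),
    mean_NDS = c(50.45, 48.40, 77.00, 83.93, 75.58,
                 13.80, 52.77, 8.29,
                 2.26, 1.74, 2.01, 1.60, 1.77, 17.23,
                 39.10, 58.84, 49.10, 39.62),
    sd_NDS   = c(3.30, 4.24, 3.31, 5.59, 5.72,
                 3.16, 2.40, 3.05,
                 0.93, 0.53, 0.68, 0.51, 0.49, 6.00,
                 7.39, 6.60, 9.29, 6.73))
}

#' Skull configuration
#'
#' @param menton_deviation signed deviation of menton (mm, + = toward left);
#'   its sign assigns the deviated side.
#' @param ds,nds named numeric vectors of the 18 per-side morphometric
#'   parameters for the deviated / non-deviated side; defaults are the
#'   deviated/non-deviated means of [default_morpho_spec()].
#' @param anb ANB angle (degrees, negative = prognathic).
#' @param pog_nperp pogonion to nasion-perpendicular distance (mm).
#' @return object of class `skull_config` with a per-side table `sides`
#'   (rows `L`, `R`).
#' @export
skull_config <- function(menton_deviation = 5.5, ds = NULL, nds = NULL,
                         anb = -2.5, pog_nperp = 3.0) {
  spec <- default_morpho_spec()
  dsv <- stats::setNames(spec$mean_DS, spec$param)
  ndv <- stats::setNames(spec$mean_NDS, spec$param)
  if (!is.null(ds)) dsv[names(ds)] <- ds
  if (!is.null(nds)) ndv[names(nds)] <- nds
  if (menton_deviation == 0)
    aj_stop("invalid_config", "menton deviation of 0 cannot assign a deviated side")
  sides <- if (menton_deviation > 0) rbind(L = dsv, R = ndv) else rbind(L = ndv, R = dsv)
  sides <- as.data.frame(sides)
  cfg <- structure(list(menton_deviation = menton_deviation, sides = sides,
                        anb = anb, pog_nperp = pog_nperp),
                   class = "skull_config")
  validate_skull_config(cfg)
  cfg
}

validate_skull_config <- function(cfg) {
  s <- cfg$sides
  pos <- c("MxH", "RH", "BL", "TCP", "SJS", "AJS", "PJS", "MJS", "LJS")
  if (any(as.matrix(s[, pos]) <= 0))
    aj_stop("invalid_config", "lengths and joint spaces must be positive")
  if (any(s$FRI <= 0 | s$FRI >= 180 | s$LRI <= 0 | s$LRI >= 180))
    aj_stop("invalid_config", "ramal inclinations must lie in (0, 180)")
  em <- as.matrix(s[, c("AES", "PES", "MES", "LES")])
  if (any(em <= 0 | em >= 89))
    aj_stop("invalid_config", "eminence steepness must lie in (0, 89)")
  if (any(s$ACA <= 0 | s$ACA >= 90))
    aj_stop("invalid_config", "axial condylar angle must lie in (0, 90)")
  invisible(cfg)
}

# ellipse helpers: point at parameter t on ellipse centred at c2 with
# semi-axes a (along d) and b (along perp)
ellipse_pt <- function(t, c2, a, d, b, perp) {
  cbind(c2[1] + a * cos(t) * d[1] + b * sin(t) * perp[1],
        c2[2] + a * cos(t) * d[2] + b * sin(t) * perp[2])
}

# random rotation via axis-angle with uniform axis
random_rigid <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  rigid3(rotation_about_axis(ax, stats::runif(1, 0, 360)),
         stats::rnorm(3, 0, 40))
}

#' Generate a synthetic skull
#'
#' Builds the landmark set in canonical head coordinates so that each
#' measurement reproduces the configured value exactly at zero noise, then
#' applies a seeded random rigid world pose (measurements are world-frame
#' invariant).
#'
#' @param config `skull_config`.
#' @param seed integer seed for the world pose.
#' @param world_pose apply a random rigid motion (default TRUE); FALSE keeps
#'   canonical head coordinates.
#' @return list with `landmarks` (`landmark_set`), `ground_truth` (per-side
#'   data frame, rows `L`/`R`, columns the 18 morphometric parameters) and
#'   `config`.
#' @export
generate_skull <- function(config, seed = 1L, world_pose = TRUE) {
  validate_skull_config(config)
  set.seed(as.integer(seed))
  pts <- list(
    Po_R = c(0, -55, 0), Po_L = c(0, 55, 0),
    Or_L = c(62, 28, 0), Or_R = c(62, -28, 0),
    Na = c(85, 0, 2), Ba = c(0, 0, -12))
  prof <- list()
  dev <- config$menton_deviation
  Me <- c(73, dev, -68)
  pts$Me <- Me
  pts$Pog <- c(85 + config$pog_nperp, 0.8 * dev, -62)
  thA <- rad(2)
  thB <- thA - rad(config$anb)
  pts$A <- pts$Na + c(28 * sin(thA), 0, -28 * cos(thA))
  pts$B <- pts$Na + c(58 * sin(thB), 0, -58 * cos(thB)); pts$B[2] <- 0.5 * dev

  for (side in c("L", "R")) {
    sigma <- if (side == "L") +1 else -1
    v <- unlist(config$sides[side, ])
    sfx <- paste0("_", side)
    pts[[paste0("U6", sfx)]] <- c(45, sigma * 26, -v["MxH"])

    # condyle: centre, poles, elliptical axial outline at pole level
    cc <- c(v["APCP"], sigma * v["TCP"], -v["VCP"])
    aca <- rad(v["ACA"])
    d2 <- c(sin(aca), sigma * cos(aca))          # medial -> lateral, axial
    perp <- c(-d2[2], d2[1])
    a_ell <- 9.5; b_ell <- 5.5
    pts[[paste0("CondLat", sfx)]] <- c(cc[1:2] + a_ell * d2, cc[3])
    pts[[paste0("CondMed", sfx)]] <- c(cc[1:2] - a_ell * d2, cc[3])
    textr <- function(u) atan2(b_ell * sum(perp * u), a_ell * sum(d2 * u))
    tt <- c(seq(0, 2 * pi, length.out = 41)[-41],
            textr(c(1, 0)), textr(c(1, 0)) + pi,
            textr(c(0, 1)), textr(c(0, 1)) + pi)
    tt <- sort(unique(round(tt %% (2 * pi), 12)))
    O2 <- ellipse_pt(tt, cc[1:2], a_ell, d2, b_ell, perp)
    prof[[paste0("condyle_axial", sfx)]] <- cbind(O2, cc[3])

    cap <- 6.5
    top <- c(cc[1:2], cc[3] + cap)
    pts[[paste0("Co", sfx)]] <- top
    pts[[paste0("FossaRoof", sfx)]] <- c(cc[1:2], cc[3] + cap + v["SJS"])

    # fossa walls: straight 8 mm profiles placed so the minimal gap from the
    # condylar prominence equals the configured joint space and the best-fit
    # inclination equals the configured steepness
    prom <- function(u) {
      t0 <- textr(u)
      drop(ellipse_pt(t0, cc[1:2], a_ell, d2, b_ell, perp))
    }
    wall <- function(p_prom2, gap, theta_deg, nhat2, dvec2, plane_coord, fixed) {
      th <- rad(theta_deg)
      m <- p_prom2 + gap * nhat2(th)
      s <- seq(-4, 4, by = 1)
      seg <- cbind(m[1] + s * dvec2(th)[1], m[2] + s * dvec2(th)[2])
      out <- matrix(NA_real_, nrow(seg), 3)
      out[, plane_coord] <- seg
      out[, setdiff(1:3, plane_coord)] <- fixed
      out
    }
    pA <- prom(c(1, 0)); pP <- prom(c(-1, 0))
    pL <- prom(c(0, sigma)); pM <- prom(c(0, -sigma))
    prof[[paste0("wall_anterior", sfx)]] <- wall(
      c(pA[1], cc[3]), v["AJS"], v["AES"],
      function(th) c(sin(th), cos(th)), function(th) c(cos(th), -sin(th)),
      c(1, 3), cc[2])
    prof[[paste0("wall_posterior", sfx)]] <- wall(
      c(pP[1], cc[3]), v["PJS"], v["PES"],
      function(th) c(-sin(th), cos(th)), function(th) c(cos(th), sin(th)),
      c(1, 3), cc[2])
    prof[[paste0("wall_medial", sfx)]] <- wall(
      c(pM[2], cc[3]), v["MJS"], v["MES"],
      function(th) c(-sigma * sin(th), cos(th)),
      function(th) c(cos(th), sigma * sin(th)),
      c(2, 3), cc[1])
    prof[[paste0("wall_lateral", sfx)]] <- wall(
      c(pL[2], cc[3]), v["LJS"], v["LES"],
      function(th) c(sigma * sin(th), cos(th)),
      function(th) c(cos(th), -sigma * sin(th)),
      c(2, 3), cc[1])

    # gonion: on the axial circle of radius BL around menton, at 3D distance
    # RH from the condylar highest point
    gamma <- rad(35)
    go_xy <- Me[1:2] + v["BL"] * c(-cos(gamma), sigma * sin(gamma))
    dxy2 <- sum((go_xy - top[1:2])^2)
    if (v["RH"]^2 <= dxy2)
      aj_stop("invalid_config", "ramal height too short for the configured body length")
    go <- c(go_xy, top[3] - sqrt(v["RH"]^2 - dxy2))
    pts[[paste0("Go", sfx)]] <- go

    # ramus border point pairs carrying the configured inclinations
    fri <- rad(v["FRI"]); lri <- rad(v["LRI"])
    p1 <- go + c(2, sigma * 4, 3)
    dlat <- c(0.08, -sigma * cos(fri), sin(fri))
    pts[[paste0("RamusLatLo", sfx)]] <- p1
    pts[[paste0("RamusLatUp", sfx)]] <- p1 + 42 * dlat
    p2 <- go + c(-3, sigma * 2, 2)
    dpost <- c(cos(lri), sigma * 0.06, sin(lri))
    pts[[paste0("RamusPostLo", sfx)]] <- p2
    pts[[paste0("RamusPostUp", sfx)]] <- p2 + 40 * dpost
  }

  P <- do.call(rbind, pts)
  rownames(P) <- names(pts)
  lm <- landmark_set(P, prof)
  if (world_pose) lm <- transform_landmarks(lm, random_rigid())
  gt <- config$sides[, MORPHO_PARAMS]
  list(landmarks = lm, ground_truth = gt, config = config)
}

#' Measure all morphometric parameters of a subject
#'
#' Runs head-frame construction, craniofacial and TMJ measurement on a
#' landmark set and returns the per-side parameter table.
#'
#' @param landmarks `landmark_set` in world coordinates.
#' @param sector_deg joint-space sector coverage (default 75).
#' @return list with `params` (rows `L`/`R`, 18 columns), `menton_deviation`,
#'   `deviated_side`, `ANB`, `pog_nperp`, `frame` (`head_frame`) and `cc`
#'   (per-side condylar centres in CHS).
#' @export
measure_morphometry <- function(landmarks, sector_deg = 75) {
  frame <- build_head_frame(landmarks)
  cm <- craniofacial_params(landmarks, frame)
  tm <- tmj_params(landmarks, frame, sector_deg = sector_deg)
  dev <- menton_deviation_and_sides(landmarks, frame)
  params <- cbind(cm[c("L", "R"), ], tm[c("L", "R"), ])[, MORPHO_PARAMS]
  list(params = params,
       menton_deviation = dev$deviation, deviated_side = dev$deviated_side,
       ANB = attr(cm, "ANB"), pog_nperp = attr(cm, "pog_nperp"),
       frame = frame, cc = attr(tm, "cc"))
}
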