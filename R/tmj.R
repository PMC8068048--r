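# Temporomandibular joint morphometry: condylar center, extracapsular
# posture, intracapsular joint spaces, axial condylar angle and articular
# eminence steepness. All operations work on the CHS projection planes:
# axial = (x, y), sagittal = (x, z), coronal = (y, z).

#' Condyle geometry for one side
#'
#' @param side `"L"` or `"R"`.
#' @param medial_pole,lateral_pole length-3 points (mm).
#' @param axial_outline ordered m x 3 polyline (>= 8 points) at pole level.
#' @param highest_point length-3 most superior condylar point.
#' @return object of class `condyle_geometry`.
#' @export
condyle_geometry <- function(side, medial_pole, lateral_pole, axial_outline,
                             highest_point) {
  if (nrow(axial_outline) < 8)
    aj_stop("schema_error", "condylar axial outline needs >= 8 points")
  structure(list(side = side, medial_pole = medial_pole,
                 lateral_pole = lateral_pole, axial_outline = axial_outline,
                 highest_point = highest_point),
            class = "condyle_geometry")
}

#' Fossa geometry for one side
#'
#' @param side `"L"` or `"R"`.
#' @param roof_point highest point of the superior wall of the glenoid fossa.
#' @param wall_profiles named list `anterior`, `posterior`, `medial`,
#'   `lateral` of ordered m x 3 polylines (>= 5 points each).
#' @return object of class `fossa_geometry`.
#' @export
fossa_geometry <- function(side, roof_point, wall_profiles) {
  need <- c("anterior", "posterior", "medial", "lateral")
  if (!all(need %in% names(wall_profiles)))
    aj_stop("schema_error", "wall_profiles must name anterior/posterior/medial/lateral")
  if (any(vapply(wall_profiles[need], nrow, 1L) < 5))
    aj_stop("schema_error", "each wall profile needs >= 5 points")
  structure(list(side = side, roof_point = roof_point,
                 wall_profiles = wall_profiles),
            class = "fossa_geometry")
}

# extract per-side condyle/fossa geometry from a CHS landmark set
condyle_from_landmarks <- function(lm, sfx) {
  condyle_geometry(sub("_", "", sfx),
                   medial_pole = get_landmark(lm, paste0("CondMed", sfx)),
                   lateral_pole = get_landmark(lm, paste0("CondLat", sfx)),
                   axial_outline = get_profile(lm, paste0("condyle_axial", sfx)),
                   highest_point = get_landmark(lm, paste0("Co", sfx)))
}

fossa_from_landmarks <- function(lm, sfx) {
  fossa_geometry(sub("_", "", sfx),
                 roof_point = get_landmark(lm, paste0("FossaRoof", sfx)),
                 wall_profiles = list(
                   anterior = get_profile(lm, paste0("wall_anterior", sfx)),
                   posterior = get_profile(lm, paste0("wall_posterior", sfx)),
                   medial = get_profile(lm, paste0("wall_medial", sfx)),
                   lateral = get_profile(lm, paste0("wall_lateral", sfx))))
}

#' Condylar center (CC)
#'
#' In the axial projection at pole level: the chord of maximal extent along
#' the medial-lateral pole direction and the chord of maximal extent along
#' its in-plane perpendicular are found over the outline vertices; CC is the
#' intersection of the two chord-supporting lines, with z set to the
#' pole-level slice (midpoint of the pole z's).
#'
#' @param condyle `condyle_geometry` in CHS.
#' @return length-3 point.
#' @export
condyle_center <- function(condyle) {
  O <- condyle$axial_outline[, 1:2, drop = FALSE]
  dirp <- condyle$lateral_pole[1:2] - condyle$medial_pole[1:2]
  if (vnorm(dirp) < 1e-9)
    aj_stop("degenerate_geometry", "condylar poles coincide in axial projection")
  dirp <- dirp / vnorm(dirp)
  perp <- c(-dirp[2], dirp[1])
  chord <- function(u) {
    pr <- drop(O %*% u)
    i <- which.max(pr); j <- which.min(pr)
    if (pr[i] - pr[j] < 1) aj_stop("degenerate_geometry", "condylar width < 1 mm")
    list(p = O[j, ], d = (O[i, ] - O[j, ]) / vnorm(O[i, ] - O[j, ]))
  }
  ml <- chord(dirp); ap <- chord(perp)
  cc2 <- intersect_lines2(ml$p, ml$d, ap$p, ap$d)
  unname(c(cc2, (condyle$medial_pole[3] + condyle$lateral_pole[3]) / 2))
}

#' Extracapsular condylar posture
#'
#' Distances of the condylar center from the three reference planes:
#' `APCP` from the coronal plane, `TCP` from the midsagittal plane, `VCP`
#' from the FH plane (all unsigned, CHS coordinate magnitudes).
#'
#' @param cc condylar center in CHS.
#' @return named numeric vector `APCP`, `TCP`, `VCP`.
#' @export
condylar_posture <- function(cc) {
  c(APCP = abs(cc[1]), TCP = abs(cc[2]), VCP = abs(cc[3]))
}

# min distance from a 2D point to a polyline + sector coverage check.
# meas_dir: the in-plane direction from the condyle toward the wall sector.
wall_gap <- function(p2, poly2, meas_dir, sector_deg, label) {
  hit <- point_polyline_dist2(p2, poly2)
  v <- hit$point - p2
  if (vnorm(v) < 1e-12) return(0)
  ang <- deg(acos(max(-1, min(1, sum(v * meas_dir) / vnorm(v)))))
  if (ang > sector_deg)
    aj_stop("profile_gap_error",
            sprintf("%s wall profile does not cover the measurement sector (%.1f deg off-axis)",
                    label, ang))
  hit$dist
}

#' Intracapsular joint spaces
#'
#' `SJS` is the vertical gap between the condylar highest point and the
#' FH-parallel tangent at the fossa roof point. `AJS`/`PJS` are minimal
#' distances from the anterior-/posterior-most outline vertex to the
#' corresponding wall profile in the sagittal (x, z) projection; `MJS`/`LJS`
#' the same along the medial/lateral directions in the coronal (y, z)
#' projection. A `profile_gap_error` is raised when the nearest wall point
#' lies more than `sector_deg` away from the measurement direction.
#'
#' @param condyle `condyle_geometry` in CHS.
#' @param fossa `fossa_geometry` in CHS.
#' @param sector_deg sector half-width for the coverage check (default 75).
#' @return named numeric vector `SJS`, `AJS`, `PJS`, `MJS`, `LJS` (mm).
#' @export
joint_spaces <- function(condyle, fossa, sector_deg = 75) {
  O <- condyle$axial_outline
  sigma <- if (condyle$side == "L") +1 else -1
  sjs <- fossa$roof_point[3] - condyle$highest_point[3]
  pa <- O[which.max(O[, 1]), ]; pp <- O[which.min(O[, 1]), ]
  pl <- O[which.max(sigma * O[, 2]), ]; pm <- O[which.min(sigma * O[, 2]), ]
  sag <- function(p) p[c(1, 3)]; cor_ <- function(p) p[c(2, 3)]
  ajs <- wall_gap(sag(pa), fossa$wall_profiles$anterior[, c(1, 3)],
                  c(1, 0), sector_deg, "anterior")
  pjs <- wall_gap(sag(pp), fossa$wall_profiles$posterior[, c(1, 3)],
                  c(-1, 0), sector_deg, "posterior")
  mjs <- wall_gap(cor_(pm), fossa$wall_profiles$medial[, c(2, 3)],
                  c(-sigma, 0), sector_deg, "medial")
  ljs <- wall_gap(cor_(pl), fossa$wall_profiles$lateral[, c(2, 3)],
                  c(sigma, 0), sector_deg, "lateral")
  c(SJS = sjs, AJS = ajs, PJS = pjs, MJS = mjs, LJS = ljs)
}

#' Axial condylar angle (ACA)
#'
#' Angle in the axial projection between the medial-to-lateral pole line and
#' the coronal trace (pure-y direction), reported as an unsigned magnitude in
#' `[0, 90]` with the sign (+ = medial pole posterior to the lateral pole)
#' stored in attribute `sign`.
#'
#' @param condyle `condyle_geometry` in CHS.
#' @return angle in degrees with attribute `sign`.
#' @export
axial_condylar_angle <- function(condyle) {
  d <- condyle$lateral_pole[1:2] - condyle$medial_pole[1:2]
  if (vnorm(d) < 1e-9)
    aj_stop("degenerate_geometry", "condylar poles coincide in axial projection")
  ang <- deg(atan2(abs(d[1]), abs(d[2])))
  out <- ang
  attr(out, "sign") <- if (d[1] > 0) +1 else if (d[1] < 0) -1 else 0
  out
}

#' Articular eminence steepness
#'
#' Best-fit-line inclinations of the four fossa wall profiles against the FH
#' plane: `AES`/`PES` from the sagittal (x, z) projection of the anterior /
#' posterior wall, `MES`/`LES` from the coronal (y, z) projection of the
#' medial / lateral wall. All in `[0, 90]` degrees.
#'
#' @param fossa `fossa_geometry` in CHS.
#' @return named numeric vector `AES`, `PES`, `MES`, `LES`.
#' @export
eminence_steepness <- function(fossa) {
  incl <- function(profile, keep) {
    P <- profile
    P2 <- cbind(P[, keep[1]], P[, keep[2]], 0)
    ln <- fit_line(P2)
    a <- deg(atan2(abs(ln$direction[2]), abs(ln$direction[1])))
    if (a >= 90 - 1e-9)
      aj_stop("degenerate_geometry", "vertical wall profile: steepness out of (0, 90)")
    a
  }
  c(AES = incl(fossa$wall_profiles$anterior, c(1, 3)),
    PES = incl(fossa$wall_profiles$posterior, c(1, 3)),
    MES = incl(fossa$wall_profiles$medial, c(2, 3)),
    LES = incl(fossa$wall_profiles$lateral, c(2, 3)))
}

#' All TMJ morphometric parameters per side
#'
#' @param landmarks `landmark_set` (world coordinates).
#' @param frame `head_frame`.
#' @param sector_deg sector half-width for joint-space coverage (default 75).
#' @return data frame with rows `L`, `R` and columns `APCP`, `TCP`, `VCP`,
#'   `SJS`, `AJS`, `PJS`, `MJS`, `LJS`, `ACA`, `AES`, `PES`, `MES`, `LES`;
#'   the per-side condylar centers (CHS) are in attribute `cc`.
#' @export
tmj_params <- function(landmarks, frame, sector_deg = 75) {
  lm <- to_chs(landmarks, frame)
  ccs <- list()
  one_side <- function(sfx) {
    cond <- condyle_from_landmarks(lm, sfx)
    foss <- fossa_from_landmarks(lm, sfx)
    cc <- condyle_center(cond)
    ccs[[sfx]] <<- cc
    aca <- axial_condylar_angle(cond)
    c(condylar_posture(cc),
      joint_spaces(cond, foss, sector_deg),
      ACA = as.numeric(aca),
      eminence_steepness(foss))
  }
  out <- rbind(L = one_side("_L"), R = one_side("_R"))
  out <- as.data.frame(out)
  attr(out, "cc") <- list(L = ccs[["_L"]], R = ccs[["_R"]])
  out
}
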