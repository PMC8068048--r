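# Reference planes (Frankfurt horizontal, midsagittal, coronal), the
# canonical head coordinate system (CHS), the five craniofacial parameters,
# menton deviation / side assignment and the eligibility filter.
#
# CHS convention: FH = {z = 0} with +z superior, MSR = {y = 0} with +y toward
# the patient's left, coronal plane (through basion) = {x = 0} with +x
# anterior. Every "frontal / sagittal / axial view" measurement is then a
# coordinate-plane projection.

#' Build the head reference frame
#'
#' The Frankfurt horizontal (FH) plane passes through both porions and the
#' left orbitale; the midsagittal reference (MSR) plane is perpendicular to
#' FH through nasion and basion; the coronal reference plane is perpendicular
#' to both, through basion. `to_chs` is the rigid transform re-expressing
#' world coordinates in the canonical head system.
#'
#' @param landmarks `landmark_set` containing `Po_R`, `Po_L`, `Or_L`, `Na`, `Ba`.
#' @return object of class `head_frame`: list with `fh_plane`, `msr_plane`,
#'   `coronal_plane` (`plane3`) and `to_chs` (`rigid3`).
#' @export
build_head_frame <- function(landmarks) {
  PoR <- get_landmark(landmarks, "Po_R"); PoL <- get_landmark(landmarks, "Po_L")
  OrL <- get_landmark(landmarks, "Or_L")
  Na <- get_landmark(landmarks, "Na"); Ba <- get_landmark(landmarks, "Ba")
  fh <- plane_from_points(PoR, PoL, OrL)
  nf <- fh$normal
  # anterior axis: basion -> nasion projected into FH
  u <- Na - Ba
  ux <- u - sum(u * nf) * nf
  if (vnorm(ux) < 1e-9)
    aj_stop("degenerate_geometry", "Na - Ba parallel to the FH normal")
  xhat <- ux / vnorm(ux)
  # superior axis: FH normal signed so that +y = z x x points to the left
  # orbitale side (Or_L defines the patient's left)
  zhat <- nf
  yhat <- cross3(zhat, xhat)
  if (sum(yhat * (OrL - Ba)) < 0) { zhat <- -zhat; yhat <- -yhat }
  R <- rbind(xhat, yhat, zhat)
  origin <- Ba - sum(zhat * (Ba - PoR)) * zhat   # Ba dropped onto FH
  to_chs <- rigid3(R, drop(-R %*% origin))
  fh_plane <- plane3(zhat, sum(zhat * PoR))
  msr_plane <- plane3(yhat, sum(yhat * Ba))
  coronal_plane <- plane3(xhat, sum(xhat * Ba))
  structure(list(fh_plane = fh_plane, msr_plane = msr_plane,
                 coronal_plane = coronal_plane, to_chs = to_chs),
            class = "head_frame")
}

#' Re-express a landmark set in canonical head coordinates
#' @param landmarks `landmark_set`.
#' @param frame `head_frame` built from the same subject.
#' @return `landmark_set` in CHS.
#' @export
to_chs <- function(landmarks, frame) transform_landmarks(landmarks, frame$to_chs)

# angle of a two-point border line in a projection, in (0, 180]:
# h = in-plane horizontal reference direction (FH trace), v = superior.
border_angle <- function(p_lower, p_upper, h_axis, v_axis = c(0, 0, 1)) {
  d <- p_upper - p_lower
  projected_angle2(sum(d * h_axis), sum(d * v_axis))
}

#' Craniofacial parameters per side
#'
#' Computed in CHS: `MxH` = |z| of the maxillary first-molar central fossa;
#' `RH` = 3D distance from the condylar highest point (`Co`) to gonion;
#' `FRI` = frontal-view (y-z) angle of the lateral ramus border line against
#' the FH trace; `LRI` = sagittal-view (x-z) angle of the posterior ramus
#' border; `BL` = menton-gonion distance in axial projection. FRI/LRI are
#' reported in (0, 180) as projected (obtuse preserved); the in-view
#' horizontal reference for FRI is the medial direction of the measured side,
#' for LRI the anterior direction.
#'
#' @param landmarks `landmark_set` (world coordinates).
#' @param frame `head_frame`.
#' @return data frame with rows `L`, `R` and columns `MxH`, `RH`, `FRI`,
#'   `LRI`, `BL` plus scalar attributes `ANB` (degrees, negative =
#'   prognathic) and `pog_nperp` (mm, anterior positive).
#' @export
craniofacial_params <- function(landmarks, frame) {
  lm <- to_chs(landmarks, frame)
  Me <- get_landmark(lm, "Me")
  one_side <- function(sfx, sigma) {
    U6 <- get_landmark(lm, paste0("U6", sfx))
    Co <- get_landmark(lm, paste0("Co", sfx))
    Go <- get_landmark(lm, paste0("Go", sfx))
    rl_lo <- get_landmark(lm, paste0("RamusLatLo", sfx))
    rl_up <- get_landmark(lm, paste0("RamusLatUp", sfx))
    rp_lo <- get_landmark(lm, paste0("RamusPostLo", sfx))
    rp_up <- get_landmark(lm, paste0("RamusPostUp", sfx))
    medial <- c(0, -sigma, 0)               # toward the midline in frontal view
    c(MxH = abs(U6[3]),
      RH = vnorm(Co - Go),
      FRI = border_angle(rl_lo, rl_up, medial),
      LRI = border_angle(rp_lo, rp_up, c(1, 0, 0)),
      BL = vnorm((Me - Go)[1:2]))
  }
  out <- rbind(L = one_side("_L", +1), R = one_side("_R", -1))
  out <- as.data.frame(out)
  Na <- get_landmark(lm, "Na"); A <- get_landmark(lm, "A")
  B <- get_landmark(lm, "B"); Pog <- get_landmark(lm, "Pog")
  # sagittal-projection angles from the vertical through nasion (anterior +)
  thA <- deg(atan2(A[1] - Na[1], Na[3] - A[3]))
  thB <- deg(atan2(B[1] - Na[1], Na[3] - B[3]))
  attr(out, "ANB") <- thA - thB
  attr(out, "pog_nperp") <- Pog[1] - Na[1]
  out
}

#' Menton deviation and deviated-side assignment
#'
#' Deviation is the signed y-coordinate of menton in CHS (+ = toward the
#' patient's left); the deviated side is the side menton points toward.
#'
#' @param landmarks `landmark_set` (world coordinates).
#' @param frame `head_frame`.
#' @return list with `deviation` (signed mm) and `deviated_side`
#'   (`"left"`/`"right"`).
#' @export
menton_deviation_and_sides <- function(landmarks, frame) {
  Me <- apply_rigid(frame$to_chs, get_landmark(landmarks, "Me"))
  if (abs(Me[2]) < 1e-9)
    aj_stop("ambiguous_side", "menton lies on the midsagittal plane")
  list(deviation = Me[2], deviated_side = if (Me[2] > 0) "left" else "right")
}

#' Eligibility filter for the asymmetry-prognathism inclusion criteria
#'
#' Pass requires all of: |menton deviation| > 3 mm (strict), pogonion to
#' nasion-perpendicular distance > 0 mm, and ANB < 0 degrees.
#'
#' @param menton_deviation signed deviation (mm).
#' @param pog_nperp pogonion to N-perpendicular distance (mm).
#' @param anb ANB angle (degrees).
#' @return list with `pass` (logical) and `reasons` (character vector, empty
#'   when passing).
#' @export
eligibility <- function(menton_deviation, pog_nperp, anb) {
  reasons <- character()
  if (!(abs(menton_deviation) > 3))
    reasons <- c(reasons, "menton deviation not > 3 mm")
  if (!(pog_nperp > 0))
    reasons <- c(reasons, "pogonion not anterior to nasion perpendicular")
  if (!(anb < 0))
    reasons <- c(reasons, "ANB not negative")
  list(pass = length(reasons) == 0, reasons = reasons)
}
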