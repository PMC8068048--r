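# Landmark container: named 3D anatomical points plus per-side surface
# profile polylines (eminence walls, condylar axial outlines) for one subject.

#' Construct a landmark set
#'
#' @param points named n x 3 matrix of landmark coordinates (mm). Required
#'   names depend on the measurement: the head frame needs `Po_R`, `Po_L`,
#'   `Or_L`, `Na`, `Ba`; see [required_landmarks()].
#' @param profiles named list of ordered m x 3 polylines: per side (`_L`,
#'   `_R`) the condylar axial outline `condyle_axial_*` and the fossa wall
#'   profiles `wall_anterior_*`, `wall_posterior_*`, `wall_medial_*`,
#'   `wall_lateral_*`.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(points, profiles = list()) {
  points <- as.matrix(points)
  if (is.null(rownames(points)) || ncol(points) != 3)
    aj_stop("schema_error", "points must be a named n x 3 matrix")
  colnames(points) <- NULL
  if (!all(is.finite(points))) aj_stop("schema_error", "non-finite landmark coordinates")
  structure(list(points = points, profiles = profiles), class = "landmark_set")
}

#' Landmark names required by the full measurement pipeline
#'
#' The source description identifies 10 craniofacial landmarks without
#' enumerating them; this name list is the package's documented
#' reconstruction (ramus border points are explicit inputs).
#'
#' @return character vector of required point names.
#' @export
required_landmarks <- function() {
  base <- c("Po_R", "Po_L", "Or_L", "Na", "Ba", "Me", "A", "B", "Pog")
  side <- c("U6", "Co", "Go", "RamusLatUp", "RamusLatLo",
            "RamusPostUp", "RamusPostLo", "CondMed", "CondLat", "FossaRoof")
  c(base, paste0(rep(side, each = 2), c("_L", "_R")))
}

#' Fetch one landmark, with a classed error when absent
#' @param lm `landmark_set`.
#' @param name landmark name.
#' @return length-3 point.
#' @export
get_landmark <- function(lm, name) {
  if (!name %in% rownames(lm$points))
    aj_stop("missing_landmark", sprintf("missing landmark '%s'", name))
  lm$points[name, ]
}

get_profile <- function(lm, name) {
  if (!name %in% names(lm$profiles))
    aj_stop("missing_landmark", sprintf("missing profile '%s'", name))
  lm$profiles[[name]]
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set: %d points, %d profiles>\n",
              nrow(x$points), length(x$profiles)))
  invisible(x)
}

# apply a rigid transform to every point and profile
transform_landmarks <- function(lm, tf) {
  lm$points <- apply_rigid(tf, lm$points)
  lm$profiles <- lapply(lm$profiles, function(p) apply_rigid(tf, p))
  lm
}

#' Mirror a landmark set across its world y = 0 plane and swap side labels
#'
#' Utility for symmetry testing: reflects all coordinates in y and exchanges
#' `_L`/`_R` suffixes (including `Po_R`/`Po_L`); `Or_L` receives the mirrored
#' right-orbitale position so the mirrored subject is anatomically valid.
#'
#' @param lm `landmark_set` expressed in canonical head coordinates.
#' @return mirrored `landmark_set`.
#' @export
mirror_landmarks <- function(lm) {
  swapnm <- function(nm) {
    out <- nm
    out[grepl("_L$", nm)] <- sub("_L$", "_R", nm[grepl("_L$", nm)])
    out[grepl("_R$", nm)] <- sub("_R$", "_L", nm[grepl("_R$", nm)])
    out
  }
  pts <- lm$points
  pts[, 2] <- -pts[, 2]
  rownames(pts) <- swapnm(rownames(pts))
  prof <- lapply(lm$profiles, function(p) { p[, 2] <- -p[, 2]; p })
  names(prof) <- swapnm(names(prof))
  landmark_set(pts, prof)
}
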