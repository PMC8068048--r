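# Jaw kinematics: per-frame rigid poses from the 4 tracked mandibular
# markers, terminal hinge-axis estimation by rotational analysis, the
# axis-horizontal zero-reference frame, condylar/incisal path tracing and the
# seven dynamic parameters (OCPL, PCPL, SCI, TCI, BA, NCPL, NIPL).
#
# Recordings are expressed in head-referenced (canonical head) coordinates:
# the tracker's head-mounted receiver frame is taken as already registered to
# the skull's reference planes.

#' Construct a motion recording
#'
#' @param movement one of `"open_close"`, `"protrusion"`,
#'   `"laterotrusion_left"`, `"laterotrusion_right"`.
#' @param time strictly increasing times (s), length n >= 20.
#' @param markers n x 12 matrix of the 4 mandibular marker positions per
#'   frame (columns m1x, m1y, m1z, ..., m4z), mm.
#' @param incisor n x 3 matrix, tracked lower-incisor midpoint.
#' @return object of class `motion_recording`.
#' @export
motion_recording <- function(movement, time, markers, incisor) {
  movement <- match.arg(movement, c("open_close", "protrusion",
                                    "laterotrusion_left", "laterotrusion_right"))
  n <- length(time)
  if (n < 20) aj_stop("schema_error", "recording needs at least 20 frames")
  if (any(diff(time) <= 0)) aj_stop("schema_error", "time must be strictly increasing")
  markers <- as.matrix(markers); incisor <- as.matrix(incisor)
  if (nrow(markers) != n || ncol(markers) != 12)
    aj_stop("schema_error", "markers must be an n x 12 matrix")
  if (nrow(incisor) != n || ncol(incisor) != 3)
    aj_stop("schema_error", "incisor must be an n x 3 matrix")
  structure(list(movement = movement, time = as.numeric(time),
                 markers = unname(markers), incisor = unname(incisor)),
            class = "motion_recording")
}

#' @export
print.motion_recording <- function(x, ...) {
  cat(sprintf("<motion_recording: %s, %d frames, %.2f s>\n",
              x$movement, length(x$time), diff(range(x$time))))
  invisible(x)
}

frame_markers <- function(rec, k) matrix(rec$markers[k, ], 4, 3, byrow = TRUE)

# per-frame rigid poses relative to the rest (intercuspal) reference, taken
# as the average of the first n_ref frames; batch least-squares registration
# (Horn's quaternion form of the Kabsch problem) in compiled code. The
# tracked incisor is rigid with the mandible and serves as a fifth
# registration point. Returns row-major rotations `R9` (n x 9) and
# translations `T` (n x 3).
recording_poses <- function(rec, n_ref = 10) {
  n_ref <- min(n_ref, length(rec$time))
  pts <- cbind(rec$markers, rec$incisor)
  ref <- matrix(colMeans(pts[seq_len(n_ref), , drop = FALSE]), 5, 3, byrow = TRUE)
  A <- sweep(ref, 2, colMeans(ref))
  if (eigen(crossprod(A), symmetric = TRUE, only.values = TRUE)$values[2] < 1e-9)
    aj_stop("degenerate_geometry", "reference markers are collinear")
  cpp_kabsch_poses(pts, ref)
}

# apply a pose array to one point: n x 3 path
apply_poses <- function(pa, p) {
  R9 <- pa$R9
  cbind(R9[, 1] * p[1] + R9[, 2] * p[2] + R9[, 3] * p[3] + pa$T[, 1],
        R9[, 4] * p[1] + R9[, 5] * p[2] + R9[, 6] * p[3] + pa$T[, 2],
        R9[, 7] * p[1] + R9[, 8] * p[2] + R9[, 9] * p[3] + pa$T[, 3])
}

pose_at <- function(pa, k) {
  list(R = matrix(pa$R9[k, ], 3, 3, byrow = TRUE), t = pa$T[k, ])
}

# centered moving average along rows (odd window; shrinking at the edges)
smooth_path <- function(P, window = 0) {
  if (window <= 1) return(P)
  if (window %% 2 == 0) window <- window + 1
  h <- (window - 1) / 2
  n <- nrow(P)
  out <- P
  cs <- apply(rbind(0, P), 2, cumsum)
  for (k in seq_len(n)) {
    hh <- min(h, k - 1, n - k)
    out[k, ] <- (cs[k + hh + 1, ] - cs[k - hh, ]) / (2 * hh + 1)
  }
  out
}

#' Estimate the terminal hinge axis from an open-close recording
#'
#' Rotational analysis: per-frame poses relative to the rest reference are
#' screened for the initial contiguous set whose rotation stays within
#' `rotation_window` and whose screw slide stays within `max_slide` (the
#' terminal-hinge phase); the common axis is the translation-weighted
#' least-squares axis over relative-pose screw axes of frame pairs spanning
#' that set. Condylar reference points are the orthogonal projections of the
#' per-side condylar centres onto the axis (or points at +/- half
#' `intercondylar_width` when centres are not supplied). The axis-horizontal
#' plane contains the axis with normal = head-vertical projected orthogonal
#' to it.
#'
#' @param rec open-close `motion_recording` in head coordinates.
#' @param cc optional list with per-side condylar centres `L`, `R`.
#' @param intercondylar_width fallback width (mm) when `cc` is absent.
#' @param rotation_window terminal-phase rotation bound (degrees, default 10).
#' @param angle_floor minimum relative rotation used for axis fitting
#'   (degrees, default 1).
#' @param max_slide maximum screw slide in the terminal phase (mm).
#' @param n_ref frames averaged for the rest reference.
#' @param max_pairs cap on frame pairs used in the least-squares fit.
#' @return object of class `hinge_frame`: `hinge_axis` (`line3`),
#'   `ref_points` (list `L`, `R`), `axis_horizontal_plane` (`plane3`),
#'   `to_ahc` (`rigid3` into axis-horizontal coordinates: +x anterior,
#'   +y toward the left along the axis, +z up; origin midway between the
#'   condylar reference points).
#' @export
estimate_hinge_axis <- function(rec, cc = NULL, intercondylar_width = 104,
                                rotation_window = 10, angle_floor = 1,
                                max_slide = 0.3, n_ref = 10, max_pairs = 150) {
  if (rec$movement != "open_close")
    aj_stop("schema_error", "hinge axis requires an open_close recording")
  pa <- recording_poses(rec, n_ref)
  R9 <- pa$R9
  angs <- deg(acos(pmax(-1, pmin(1, (R9[, 1] + R9[, 5] + R9[, 9] - 1) / 2))))
  # per-frame screw direction (from the skew part) and slide
  sk <- cbind(R9[, 8] - R9[, 6], R9[, 3] - R9[, 7], R9[, 4] - R9[, 2])
  nsk <- sqrt(rowSums(sk^2))
  slide <- rowSums(pa$T * sk) / pmax(nsk, 1e-12)
  # initial contiguous terminal-hinge candidate set
  K <- 0
  for (k in seq_along(angs)) {
    if (angs[k] > rotation_window) break
    if (angs[k] >= angle_floor && abs(slide[k]) > max_slide) break
    K <- k
  }
  idx <- which(angs[seq_len(K)] >= angle_floor)
  if (length(idx) < 1)
    aj_stop("no_rotation_phase", "no frames with usable rotation in the terminal phase")
  # frame pairs spanning the window (both endpoints noisy -> average both)
  lo <- c(which(angs[seq_len(K)] < angle_floor / 2), 1)
  pairs <- expand.grid(i = unique(c(1, lo)), j = idx)
  pairs <- pairs[pairs$j > pairs$i, , drop = FALSE]
  extra <- expand.grid(i = idx, j = idx)
  extra <- extra[extra$j > extra$i, , drop = FALSE]
  pairs <- unique(rbind(pairs, extra))
  if (nrow(pairs) > max_pairs)
    pairs <- pairs[unique(round(seq(1, nrow(pairs), length.out = max_pairs))), ]
  M <- matrix(0, 3, 3); dref <- NULL
  A <- matrix(0, 3, 3); b <- rep(0, 3); wsum <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    Ri <- matrix(R9[i, ], 3, 3, byrow = TRUE)
    Rj <- matrix(R9[j, ], 3, 3, byrow = TRUE)
    Rrel <- Rj %*% t(Ri)
    th <- rotation_angle_deg(Rrel)
    if (th < angle_floor) next
    trel <- pa$T[j, ] - drop(Rrel %*% pa$T[i, ])
    skr <- c(Rrel[3, 2] - Rrel[2, 3], Rrel[1, 3] - Rrel[3, 1], Rrel[2, 1] - Rrel[1, 2])
    d <- skr / vnorm(skr)
    sl <- sum(trel * d)
    tperp <- trel - sl * d
    p <- 0.5 * (tperp + cross3(d, tperp) / tan(rad(th) / 2))
    if (is.null(dref)) dref <- d
    if (sum(d * dref) < 0) d <- -d
    w <- rad(th)^2
    M <- M + w * (d %o% d)
    Pd <- diag(3) - d %o% d
    A <- A + w * Pd
    b <- b + w * drop(Pd %*% p)
    wsum <- wsum + w
  }
  if (wsum == 0)
    aj_stop("no_rotation_phase", "no usable frame pairs for axis estimation")
  ev <- eigen(M, symmetric = TRUE)
  dir <- ev$vectors[, 1]
  if (sum(dir * dref) < 0) dir <- -dir
  pt <- drop(solve(A + 1e-12 * diag(3), b))
  pt <- pt - sum(pt * dir) * dir
  axis <- line3(pt, dir)
  hinge_frame(axis, cc = cc, intercondylar_width = intercondylar_width)
}

#' Build the axis-horizontal reference frame from a hinge axis
#'
#' @param axis `line3` hinge axis in head coordinates.
#' @param cc optional list of condylar centres `L`, `R` to project.
#' @param intercondylar_width fallback width (mm).
#' @param head_vertical the superior direction (default CHS +z).
#' @return `hinge_frame` (see [estimate_hinge_axis()]).
#' @export
hinge_frame <- function(axis, cc = NULL, intercondylar_width = 104,
                        head_vertical = c(0, 0, 1)) {
  d <- axis$direction
  if (d[2] < 0) d <- -d              # +y toward the patient's left
  proj <- function(p) axis$point + sum((p - axis$point) * d) * d
  if (!is.null(cc)) {
    refL <- proj(cc$L); refR <- proj(cc$R)
  } else {
    mid0 <- proj(c(0, 0, 0))
    refL <- mid0 + intercondylar_width / 2 * d
    refR <- mid0 - intercondylar_width / 2 * d
  }
  zv <- head_vertical - sum(head_vertical * d) * d
  if (vnorm(zv) < 1e-9)
    aj_stop("degenerate_geometry", "hinge axis parallel to head vertical")
  zhat <- zv / vnorm(zv)
  xhat <- cross3(d, zhat)
  origin <- (refL + refR) / 2
  R <- rbind(xhat, d, zhat)
  structure(list(hinge_axis = line3(axis$point, d),
                 ref_points = list(L = refL, R = refR),
                 axis_horizontal_plane = plane3(zhat, sum(zhat * origin)),
                 to_ahc = rigid3(R, drop(-R %*% origin))),
            class = "hinge_frame")
}

#' Condylar and incisal paths in axis-horizontal coordinates
#'
#' Applies each frame's pose to the condylar reference points, takes the
#' tracked incisor directly, optionally smooths with a centred moving
#' average, and re-expresses everything in axis-horizontal coordinates
#' (z = 0 on the axis-horizontal plane, +x anterior).
#'
#' @param rec `motion_recording`.
#' @param hinge `hinge_frame`.
#' @param smoothing_window odd moving-average window in frames (0 = off).
#' @param n_ref frames averaged for the rest reference.
#' @param poses optional precomputed per-frame poses (internal reuse).
#' @return list with `L`, `R`, `incisor` (n x 3 paths), `time`, `movement`.
#' @export
condylar_paths <- function(rec, hinge, smoothing_window = 0, n_ref = 10,
                           poses = NULL) {
  if (is.null(poses)) poses <- recording_poses(rec, n_ref)
  PL <- apply_poses(poses, hinge$ref_points$L)
  PR <- apply_poses(poses, hinge$ref_points$R)
  PI <- rec$incisor
  PL <- smooth_path(PL, smoothing_window)
  PR <- smooth_path(PR, smoothing_window)
  PI <- smooth_path(PI, smoothing_window)
  list(L = apply_rigid(hinge$to_ahc, PL),
       R = apply_rigid(hinge$to_ahc, PR),
       incisor = apply_rigid(hinge$to_ahc, PI),
       time = rec$time, movement = rec$movement)
}

#' Resample a path at a minimum arc step
#'
#' Walks the polyline keeping only points at least `step` mm from the last
#' kept point (the final point is always kept). In noisy recordings the
#' slow-motion phases contribute many near-zero true steps whose chords are
#' noise-dominated; resampling removes that accumulation. `step = 0` (the
#' default everywhere) returns the path unchanged.
#'
#' @param path n x 3 matrix.
#' @param step minimum chord step in mm (0 = off).
#' @return resampled path.
#' @export
resample_path <- function(path, step = 0) {
  path <- rbind(path)
  if (step <= 0 || nrow(path) < 3) return(path)
  keep <- 1L
  last <- path[1, ]
  for (k in 2:nrow(path)) {
    if (sqrt(sum((path[k, ] - last)^2)) >= step) {
      keep <- c(keep, k)
      last <- path[k, ]
    }
  }
  if (keep[length(keep)] != nrow(path)) keep <- c(keep, nrow(path))
  path[keep, , drop = FALSE]
}

#' Path length of the monotone leg
#'
#' Cumulative chord length from the first frame to the frame of maximal
#' displacement from the start, after optional moving-average smoothing.
#'
#' @param path n x 3 matrix (or fewer columns).
#' @param smoothing_window odd moving-average window (0 = off).
#' @return length in mm (0 for an empty or single-point path).
#' @export
path_length <- function(path, smoothing_window = 0) {
  if (!is.matrix(path)) path <- rbind(path)
  n <- nrow(path)
  if (n < 2) return(0)
  path <- smooth_path(path, smoothing_window)
  d1 <- path[, 1] - path[1, 1]; d2 <- path[, 2] - path[1, 2]
  d3 <- path[, 3] - path[1, 3]
  kmax <- which.max(d1 * d1 + d2 * d2 + d3 * d3)
  if (kmax < 2) return(0)
  i <- seq_len(kmax - 1)
  sum(sqrt(diff(d1[seq_len(kmax)])^2 + diff(d2[seq_len(kmax)])^2 +
             diff(d3[seq_len(kmax)])^2))
}

# monotone leg of a path (up to maximal displacement from start)
monotone_leg <- function(path) {
  d1 <- path[, 1] - path[1, 1]; d2 <- path[, 2] - path[1, 2]
  d3 <- path[, 3] - path[1, 3]
  path[seq_len(which.max(d1 * d1 + d2 * d2 + d3 * d3)), , drop = FALSE]
}

#' Trim the pre-movement rest phase from a path
#'
#' With noisy recordings the rest (dwell) frames before motion onset
#' accumulate spurious chord length; this trims the path to start at the last
#' frame whose displacement from the initial position is below
#' `onset_tol / 3`, preceding the first frame exceeding `onset_tol`. With
#' `onset_tol = 0` (the default everywhere) the path is returned unchanged,
#' so noise-free analyses stay exact.
#'
#' @param path n x 3 matrix.
#' @param onset_tol displacement threshold in mm (0 = no trimming).
#' @return trimmed path.
#' @export
onset_trim <- function(path, onset_tol = 0) {
  path <- rbind(path)
  k0 <- onset_index(path, onset_tol)
  path[k0:nrow(path), , drop = FALSE]
}

# index of the last rest frame before motion onset (1 when not detectable)
onset_index <- function(path, onset_tol) {
  if (onset_tol <= 0 || nrow(path) < 6) return(1L)
  # displacement from a robust rest position (the very first frame may sit at
  # a shrunken smoothing window and carry raw noise)
  p0 <- colMeans(path[1:5, , drop = FALSE])
  disp <- sqrt(rowSums(sweep(path, 2, p0)^2))
  k1 <- which(disp > onset_tol)[1]
  if (is.na(k1) || k1 <= 2) return(1L)
  low <- which(disp[seq_len(k1 - 1)] <= onset_tol / 3)
  if (length(low)) max(low) else 1L
}

#' Sagittal and transverse condylar inclination of a protrusive path
#'
#' `SCI` is the angle in `[0, 90]` between the total-least-squares line of
#' the sagittal (x, z) projection and the axis-horizontal plane; `TCI` is the
#' signed angle between the fitted axial (x, y) direction and anterior,
#' positive toward the medial side of the measured condyle.
#'
#' @param path n x 3 condylar path in axis-horizontal coordinates.
#' @param side `"L"` or `"R"` (fixes the medial direction).
#' @return named vector `SCI`, `TCI` (degrees).
#' @export
condylar_inclinations <- function(path, side) {
  sigma <- if (side == "L") +1 else -1
  leg <- monotone_leg(path)
  ex <- (leg[nrow(leg), 1] - leg[1, 1])^2 + (leg[nrow(leg), 2] - leg[1, 2])^2 +
    (leg[nrow(leg), 3] - leg[1, 3])^2
  if (ex < 1)
    aj_stop("degenerate_path", "protrusive path extent below 1 mm")
  dsag <- tls_dir2(leg[, 1], leg[, 3])
  sci <- deg(atan2(abs(dsag[2]), abs(dsag[1])))
  dax <- tls_dir2(leg[, 1], leg[, 2])
  if (dax[1] < 0) dax <- -dax        # orient anteriorly
  tci <- deg(atan2(-sigma * dax[2], dax[1]))
  c(SCI = sci, TCI = tci)
}

#' Bennett angle
#'
#' Locates by linear interpolation the point at cumulative path length
#' exactly 1 mm and reports the axial-projection angle between anterior (+x)
#' and the chord from the start to that point, unsigned in `[0, 90]`.
#'
#' @param path n x 3 non-working condylar path in axis-horizontal coordinates.
#' @return angle in degrees.
#' @export
bennett_angle <- function(path) {
  path <- rbind(path)
  seg <- diff(path)
  cl <- c(0, cumsum(sqrt(rowSums(seg^2))))
  if (max(cl) < 1)
    aj_stop("path_too_short", "path shorter than 1 mm")
  k <- which(cl >= 1)[1]
  t <- (1 - cl[k - 1]) / (cl[k] - cl[k - 1])
  p1 <- path[k - 1, ] + t * (path[k, ] - path[k - 1, ])
  chord <- p1 - path[1, ]
  unname(deg(atan2(abs(chord[2]), abs(chord[1]))))
}

#' The seven dynamic parameters from the four border movements
#'
#' `OCPL` per side from the open-close condylar paths; `PCPL`, `SCI`, `TCI`
#' per side from protrusion; for a laterotrusion toward side W the
#' non-working parameters `NCPL` (condylar), `BA` and `NIPL` (incisal) are
#' computed from the contralateral paths and assigned to the non-working
#' side.
#'
#' @param recordings named list with `open_close`, `protrusion`,
#'   `laterotrusion_left`, `laterotrusion_right` (`motion_recording`s).
#' @param hinge `hinge_frame`.
#' @param smoothing_window odd moving-average window (0 = off).
#' @param onset_tol rest-phase trimming threshold in mm (see [onset_trim()];
#'   0 = off, keeping zero-noise analyses exact).
#' @param resample_step minimum arc step for path resampling in mm (see
#'   [resample_path()]; 0 = off).
#' @param n_ref frames averaged for the rest reference.
#' @return data frame, rows `L`/`R`, columns `OCPL`, `PCPL`, `SCI`, `TCI`,
#'   `BA`, `NCPL`, `NIPL`.
#' @export
kinematic_record <- function(recordings, hinge, smoothing_window = 0,
                             onset_tol = 0, resample_step = 0, n_ref = 10) {
  need <- c("open_close", "protrusion", "laterotrusion_left", "laterotrusion_right")
  miss <- setdiff(need, names(recordings))
  if (length(miss))
    aj_stop("missing_movement", paste("missing movement(s):", paste(miss, collapse = ", ")))
  poses <- lapply(recordings[need], recording_poses, n_ref = n_ref)
  paths <- lapply(need, function(mv)
    condylar_paths(recordings[[mv]], hinge, smoothing_window = smoothing_window,
                   n_ref = n_ref, poses = poses[[mv]]))
  names(paths) <- need
  trim <- function(P) resample_path(onset_trim(P, onset_tol), resample_step)
  # the Bennett angle probes a ~1 mm feature near motion onset where the jaw
  # moves slowly; a longer matched window recovers the chord endpoints
  ba_win <- if (smoothing_window > 0) 7 * smoothing_window else 0
  out <- data.frame(OCPL = rep(NA_real_, 2), PCPL = NA_real_, SCI = NA_real_,
                    TCI = NA_real_, BA = NA_real_, NCPL = NA_real_, NIPL = NA_real_,
                    row.names = c("L", "R"))
  for (s in c("L", "R")) {
    out[s, "OCPL"] <- path_length(trim(paths$open_close[[s]]))
    prot <- onset_trim(paths$protrusion[[s]], onset_tol)
    out[s, "PCPL"] <- path_length(resample_path(prot, resample_step))
    # inclinations from the time-sampled (unresampled) path: arc-uniform
    # reweighting of a curved path shifts the fitted direction
    out[s, c("SCI", "TCI")] <- condylar_inclinations(prot, s)
    # non-working side s <=> laterotrusion toward the opposite (working) side
    mv <- paste0("laterotrusion_", if (s == "L") "right" else "left")
    lat <- paths[[mv]]
    nwpath <- trim(lat[[s]])
    out[s, "NCPL"] <- path_length(nwpath)
    if (ba_win > 0) {
      latba <- condylar_paths(recordings[[mv]], hinge, smoothing_window = ba_win,
                              n_ref = n_ref, poses = poses[[mv]])
      out[s, "BA"] <- bennett_angle(monotone_leg(onset_trim(latba[[s]], onset_tol)))
    } else {
      out[s, "BA"] <- bennett_angle(monotone_leg(trim(lat[[s]])))
    }
    out[s, "NIPL"] <- path_length(trim(lat$incisor))
  }
  out
}
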