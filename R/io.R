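# Readers and writers for the interchange formats:
#   landmark points CSV: name,x,y,z
#   profile CSV:         profile,seq,x,y,z      (ordered polylines)
#   landmark JSON:       {"points": {name: [x,y,z]}, "profiles": {name: [[..]]}}
#   trajectory CSV:      "# movement: <label>" header line, then
#                        time,m1x,m1y,m1z,...,m4z,incx,incy,incz
# Validation errors carry the offending field/row in the message.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a landmark set to CSV files
#'
#' @param lm `landmark_set`.
#' @param points_file path for the points CSV (`name,x,y,z`).
#' @param profiles_file path for the profiles CSV (`profile,seq,x,y,z`);
#'   omitted when `NULL`.
#' @return invisibly, the paths written.
#' @export
write_landmarks <- function(lm, points_file, profiles_file = NULL) {
  pts <- data.frame(name = rownames(lm$points),
                    x = fmt_num(lm$points[, 1]),
                    y = fmt_num(lm$points[, 2]),
                    z = fmt_num(lm$points[, 3]))
  utils::write.csv(pts, points_file, row.names = FALSE, quote = FALSE)
  if (!is.null(profiles_file)) {
    rows <- do.call(rbind, lapply(names(lm$profiles), function(nm) {
      P <- lm$profiles[[nm]]
      data.frame(profile = nm, seq = seq_len(nrow(P)),
                 x = fmt_num(P[, 1]), y = fmt_num(P[, 2]), z = fmt_num(P[, 3]))
    }))
    utils::write.csv(rows, profiles_file, row.names = FALSE, quote = FALSE)
  }
  invisible(c(points_file, profiles_file))
}

#' Read a landmark set from CSV files
#'
#' @param points_file CSV with columns `name,x,y,z`.
#' @param profiles_file optional CSV with columns `profile,seq,x,y,z`.
#' @param require character vector of landmark names that must be present
#'   (default none).
#' @return `landmark_set`.
#' @export
read_landmarks <- function(points_file, profiles_file = NULL, require = character()) {
  d <- utils::read.csv(points_file, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(d)))
    aj_stop("schema_error", sprintf("landmark CSV must have columns %s",
                                    paste(need, collapse = ",")))
  bad <- which(!is.finite(d$x) | !is.finite(d$y) | !is.finite(d$z))
  if (length(bad))
    aj_stop("schema_error", sprintf("non-numeric coordinates at row %d", bad[1] + 1))
  if (anyDuplicated(d$name))
    aj_stop("schema_error", sprintf("duplicated landmark name '%s'",
                                    d$name[duplicated(d$name)][1]))
  miss <- setdiff(require, d$name)
  if (length(miss))
    aj_stop("missing_landmark", sprintf("missing required landmark '%s'", miss[1]))
  pts <- as.matrix(d[, c("x", "y", "z")])
  rownames(pts) <- d$name
  profiles <- list()
  if (!is.null(profiles_file)) {
    p <- utils::read.csv(profiles_file, stringsAsFactors = FALSE)
    if (!all(c("profile", "seq", "x", "y", "z") %in% names(p)))
      aj_stop("schema_error", "profile CSV must have columns profile,seq,x,y,z")
    for (nm in unique(p$profile)) {
      q <- p[p$profile == nm, ]
      q <- q[order(q$seq), ]
      if (any(diff(q$seq) != 1))
        aj_stop("schema_error", sprintf("profile '%s' has non-consecutive seq", nm))
      profiles[[nm]] <- unname(as.matrix(q[, c("x", "y", "z")]))
    }
  }
  landmark_set(pts, profiles)
}

#' Write a landmark set to JSON
#' @param lm `landmark_set`.
#' @param file output path.
#' @return invisibly, the path.
#' @export
write_landmarks_json <- function(lm, file) {
  obj <- list(points = stats::setNames(lapply(seq_len(nrow(lm$points)),
                                              function(i) unname(lm$points[i, ])),
                                       rownames(lm$points)),
              profiles = lapply(lm$profiles, function(P)
                lapply(seq_len(nrow(P)), function(i) unname(P[i, ]))))
  jsonlite::write_json(obj, file, auto_unbox = FALSE, digits = NA)
  invisible(file)
}

#' Read a landmark set from JSON
#' @param file JSON path (see [write_landmarks_json()] for the schema).
#' @return `landmark_set`.
#' @export
read_landmarks_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (is.null(obj$points)) aj_stop("schema_error", "JSON lacks a 'points' object")
  pts <- do.call(rbind, obj$points)
  rownames(pts) <- names(obj$points)
  profs <- lapply(obj$profiles, function(P) if (is.list(P)) do.call(rbind, P) else P)
  landmark_set(pts, profs %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a motion recording to CSV
#'
#' The first line names the movement (`# movement: <label>`); the table has
#' fixed column order `time,m1x,...,m4z,incx,incy,incz`.
#'
#' @param rec `motion_recording`.
#' @param file output path.
#' @return invisibly, the path.
#' @export
write_trajectory <- function(rec, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# movement: %s", rec$movement), con)
  hdr <- c("time", paste0("m", rep(1:4, each = 3), c("x", "y", "z")),
           "incx", "incy", "incz")
  writeLines(paste(hdr, collapse = ","), con)
  M <- cbind(rec$time, rec$markers, rec$incisor)
  writeLines(apply(M, 1, function(r) paste(fmt_num(r), collapse = ",")), con)
  invisible(file)
}

#' Read a motion recording from CSV
#' @param file path written by [write_trajectory()].
#' @return `motion_recording`.
#' @export
read_trajectory <- function(file) {
  first <- readLines(file, n = 1)
  if (!grepl("^# movement: ", first))
    aj_stop("schema_error", "trajectory CSV must start with '# movement: <label>'")
  movement <- sub("^# movement: ", "", first)
  d <- utils::read.csv(file, skip = 1, stringsAsFactors = FALSE)
  hdr <- c("time", paste0("m", rep(1:4, each = 3), c("x", "y", "z")),
           "incx", "incy", "incz")
  if (!identical(names(d), hdr))
    aj_stop("schema_error", "trajectory CSV has wrong columns or column order")
  if (any(diff(d$time) <= 0)) {
    k <- which(diff(d$time) <= 0)[1]
    aj_stop("schema_error", sprintf("non-monotone time at row %d", k + 3))
  }
  motion_recording(movement, d$time, as.matrix(d[, 2:13]), as.matrix(d[, 14:16]))
}

#' Write the statistical reports of a pipeline run
#'
#' Emits CSV files in the layout of the published tables: the power /
#' sample-size analysis, the paired side comparison, the correlation tables
#' and the per-side rotated loading matrices, plus a machine-readable run
#' manifest.
#'
#' @param results result list from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_reports <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(results$power, "power_analysis.csv")
  wr(results$paired, "paired_comparison.csv")
  for (side in c("DS", "NDS")) {
    ct <- results$correlations[[side]]
    df <- data.frame(variable = rownames(ct$r), round(ct$r, 4))
    wr(df, sprintf("correlation_r_%s.csv", side))
    dfp <- data.frame(variable = rownames(ct$p), round(ct$p, 4))
    wr(dfp, sprintf("correlation_p_%s.csv", side))
    fm <- results$factors[[side]]
    wr(data.frame(variable = rownames(fm$loadings), round(fm$loadings, 3)),
       sprintf("factor_loadings_%s.csv", side))
  }
  manifest <- list(package = "asymjaw",
                   version = as.character(utils::packageVersion("asymjaw")),
                   seed = results$config$seed,
                   n_subjects = results$config$n_subjects,
                   n_excluded = length(results$excluded),
                   options = results$config[c("marker_noise_sd", "n_repeats",
                                              "smoothing_window", "onset_tol",
                                              "resample_step", "alpha",
                                              "n_components")])
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, file.path(dir, "run_manifest.json")))
}
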