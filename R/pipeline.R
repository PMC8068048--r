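# End-to-end pipeline: synthetic cohort -> per-subject measurement (head
# frame, morphometry, hinge-axis kinematics) -> deviated/non-deviated
# reorganization with eligibility filtering -> statistics stage (paired
# comparison, correlation tables, PCA + varimax, power analysis) -> report
# files. Deterministic given the seed.

#' Pipeline configuration
#'
#' @param n_subjects number of subjects in a synthetic cohort run.
#' @param seed integer master seed; all sub-seeds derive from it.
#' @param spec `effect_spec` for the cohort draws.
#' @param marker_noise_sd sensor noise (mm).
#' @param frame_rate recording sample rate (Hz). The cohort default (25 Hz)
#'   keeps simulation sizes tractable; per-subject analyses use 100 Hz.
#' @param n_repeats recordings acquired per movement; parameter estimates are
#'   averaged over repeats (duplicate-acquisition protocol).
#' @param smoothing_window,onset_tol,resample_step kinematic path-processing
#'   options (see [kinematic_record()]); the defaults suit noisy recordings
#'   and are all switched off automatically when `marker_noise_sd = 0`.
#' @param rotation_window hinge-phase screening window (degrees).
#' @param alpha two-sided significance level of the statistics stage.
#' @param n_components factor-analysis component count.
#' @param kaiser_normalize Kaiser normalization for the varimax rotation.
#' @param fdr apply Benjamini-Hochberg adjustment to correlation p-values
#'   (off by default, matching an unadjusted presentation).
#' @param power_vars variables for the representative power analysis.
#' @param output_dir optional report directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 30, seed = 1L, spec = effect_spec(),
                            marker_noise_sd = 0.05, frame_rate = 25,
                            n_repeats = 1,
                            smoothing_window = 15, onset_tol = 0.15,
                            resample_step = 0.3, rotation_window = 10,
                            alpha = 0.05, n_components = 4,
                            kaiser_normalize = TRUE, fdr = FALSE,
                            power_vars = c("AES", "PCPL", "NCPL"),
                            output_dir = NULL) {
  if (marker_noise_sd == 0) {
    smoothing_window <- 0; onset_tol <- 0; resample_step <- 0
  }
  structure(list(n_subjects = n_subjects, seed = as.integer(seed), spec = spec,
                 marker_noise_sd = marker_noise_sd, frame_rate = frame_rate,
                 n_repeats = n_repeats, smoothing_window = smoothing_window,
                 onset_tol = onset_tol, resample_step = resample_step,
                 rotation_window = rotation_window, alpha = alpha,
                 n_components = n_components,
                 kaiser_normalize = kaiser_normalize, fdr = fdr,
                 power_vars = power_vars, output_dir = output_dir),
            class = "pipeline_config")
}

# durations scaled to the frame rate tier: full-length slow border movements
# at >= 100 Hz, shorter legs at cohort rates
motion_config_for <- function(config, deviated_side, ds = NULL, nds = NULL) {
  motion_config(deviated_side = deviated_side, ds = ds, nds = nds,
                marker_noise_sd = config$marker_noise_sd,
                frame_rate = config$frame_rate)
}

#' Measure one subject end to end
#'
#' Runs head-frame construction, craniofacial and TMJ morphometry, the
#' eligibility filter, hinge-axis estimation and kinematic parameter
#' extraction (averaged over repeated recordings), and reorganizes the
#' per-side values into deviated/non-deviated columns.
#'
#' @param landmarks `landmark_set` (world coordinates).
#' @param repeats list of recording sets (each a named list of the four
#'   movements), independent acquisitions of the same movements.
#' @param config `pipeline_config` (analysis options).
#' @return object of class `subject_record`: list with `params` (named
#'   vector `<var>_DS` / `<var>_NDS`), `eligibility`, `deviated_side`,
#'   `menton_deviation`, `ANB`, `pog_nperp`, `morpho`, `kinematic`, `hinge`.
#' @export
measure_subject <- function(landmarks, repeats, config = pipeline_config()) {
  mm <- measure_morphometry(landmarks)
  elig <- eligibility(mm$menton_deviation, mm$pog_nperp, mm$ANB)
  krs <- lapply(repeats, function(recs) {
    hinge <- estimate_hinge_axis(recs$open_close, cc = mm$cc,
                                 rotation_window = config$rotation_window)
    list(hinge = hinge,
         kr = kinematic_record(recs, hinge,
                               smoothing_window = config$smoothing_window,
                               onset_tol = config$onset_tol,
                               resample_step = config$resample_step))
  })
  kin <- Reduce(`+`, lapply(krs, function(x) as.matrix(x$kr))) / length(krs)
  kin <- as.data.frame(kin)
  ds <- if (mm$deviated_side == "left") "L" else "R"
  nds <- setdiff(c("L", "R"), ds)
  all <- cbind(mm$params, kin)
  params <- c(stats::setNames(as.numeric(all[ds, ]), paste0(names(all), "_DS")),
              stats::setNames(as.numeric(all[nds, ]), paste0(names(all), "_NDS")))
  structure(list(params = params, eligibility = elig,
                 deviated_side = mm$deviated_side,
                 menton_deviation = mm$menton_deviation,
                 ANB = mm$ANB, pog_nperp = mm$pog_nperp,
                 morpho = mm$params, kinematic = kin,
                 hinge = krs[[1]]$hinge),
            class = "subject_record")
}

# the 16-variable set carried into the factor analysis (posterior/lateral
# joint spaces and eminence walls excluded)
FACTOR_VARS <- c("NCPL", "PCPL", "AES", "NIPL", "FRI", "SCI", "OCPL", "MES",
                 "MJS", "SJS", "ACA", "LRI", "BL", "RH", "MxH", "AJS")

TF_VARS <- c("OCPL", "PCPL", "SCI", "NIPL", "NCPL")
CM_VARS <- c("MxH", "RH", "FRI", "LRI", "BL")
TM_VARS <- c("AJS", "SJS", "PJS", "MJS", "LJS", "ACA", "AES", "PES", "MES", "LES")

#' Statistics stage on a measured cohort table
#'
#' Paired deviated- vs non-deviated-side comparison of all variables,
#' Pearson correlation tables between the condylar-function variables and
#' the craniofacial / TMJ morphometric variables per side, PCA with varimax
#' rotation per side, and the representative paired power analysis.
#'
#' @param cohort cohort table (`<var>_DS` / `<var>_NDS` columns).
#' @param config `pipeline_config`.
#' @return list with `paired`, `correlations` (per side: `r`, `p`, `n`),
#'   `factors` (per side `factor_model`), `power` (data frame).
#' @export
analyze_cohort <- function(cohort, config = pipeline_config()) {
  paired <- paired_compare(cohort)
  correlations <- list(); factors <- list()
  for (side in c("DS", "NDS")) {
    ct <- correlation_table(cohort, c(CM_VARS, TM_VARS), TF_VARS, side)
    if (config$fdr) ct$p[] <- stats::p.adjust(ct$p, method = "BH")
    correlations[[side]] <- ct
    factors[[side]] <- factor_analysis(cohort, FACTOR_VARS, side,
                                       k = config$n_components,
                                       kaiser_normalize = config$kaiser_normalize)
  }
  power <- do.call(rbind, lapply(config$power_vars, function(v) {
    d <- cohort[[paste0(v, "_DS")]] - cohort[[paste0(v, "_NDS")]]
    dz <- abs(mean(d)) / stats::sd(d)
    data.frame(variable = v, effect_size_dz = dz,
               power_at_n = power_paired_t(dz, nrow(cohort), config$alpha),
               n_for_80 = min_n_paired_t(dz, 0.80, config$alpha))
  }))
  list(paired = paired, correlations = correlations, factors = factors,
       power = power)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Draws a cohort, materializes each subject (skull landmarks and the four
#' border-movement recordings with sensor noise), measures every subject,
#' excludes ineligible ones with logged reasons, runs the statistics stage
#' and optionally writes report files. Deterministic given `config$seed`.
#'
#' @param config `pipeline_config`.
#' @return list with `cohort` (measured cohort table), `subjects` (list of
#'   `subject_record`), `excluded` (named list of reason vectors),
#'   `ground_truth` (drawn parameter table), plus the [analyze_cohort()]
#'   results (`paired`, `correlations`, `factors`, `power`) and `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  gen <- generate_cohort(config$n_subjects, config$spec, seed = config$seed)
  subjects <- list(); excluded <- list(); rows <- list()
  for (i in seq_along(gen$subjects)) {
    sub <- gen$subjects[[i]]
    scfg <- skull_config(menton_deviation = sub$menton_deviation,
                         ds = sub$ds[MORPHO_PARAMS], nds = sub$nds[MORPHO_PARAMS],
                         anb = sub$anb, pog_nperp = sub$pog_nperp)
    sk <- generate_skull(scfg, seed = (config$seed %% 100000L) * 1009L + i)
    mcfg <- motion_config_for(config, sub$deviated_side,
                              ds = sub$ds[KINEMATIC_PARAMS],
                              nds = sub$nds[KINEMATIC_PARAMS])
    rec <- generate_recordings(sk$landmarks, mcfg,
                               seed = (config$seed %% 100000L) * 2003L + i,
                               n_repeats = config$n_repeats)
    sr <- tryCatch(measure_subject(sk$landmarks, rec$repeats, config),
                   error = function(e) e)
    if (inherits(sr, "error")) {
      excluded[[as.character(i)]] <- conditionMessage(sr)
      next
    }
    if (!sr$eligibility$pass) {
      excluded[[as.character(i)]] <- sr$eligibility$reasons
      next
    }
    subjects[[length(subjects) + 1]] <- sr
    rows[[length(rows) + 1]] <-
      as.data.frame(c(list(subject = i, deviated_side = sr$deviated_side),
                      as.list(sr$params)))
  }
  if (length(rows) < 3)
    aj_stop("invalid_config", "fewer than 3 eligible subjects")
  cohort <- do.call(rbind, rows)
  res <- analyze_cohort(cohort, config)
  out <- c(list(cohort = cohort, subjects = subjects, excluded = excluded,
                ground_truth = gen$table, config = config), res)
  if (!is.null(config$output_dir)) write_reports(out, config$output_dir)
  out
}
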