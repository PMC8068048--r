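# Cohort generator: per-subject parameter draws with bilateral (paired)
# structure, a latent morpho-functional factor on the deviated side, and
# truncation to geometric invariants; plus the cohort-table container the
# statistics stage consumes.

#' Cohort effect specification
#'
#' Per-side means/SDs of all 25 variables (18 morphometric + 7 dynamic),
#' the deviated/non-deviated pairing correlation, and the latent factor
#' shared by `FRI`, `AES`, `MJS`, `ACA` and `PCPL` on the deviated side
#' (inducing their positive cross-correlations). With `null = TRUE` both
#' sides share the pooled means/SDs (no interside effect), for type-I-error
#' calibration.
#'
#' @param pairing_correlation correlation between the DS and NDS values of a
#'   variable (default 0.5).
#' @param latent_loading loading of the shared deviated-side factor
#'   (default 0.6; 0 disables it).
#' @param null logical; erase all interside differences.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(pairing_correlation = 0.5, latent_loading = 0.6,
                        null = FALSE) {
  tab <- rbind(default_morpho_spec(), default_kinematic_spec())
  if (null) {
    tab$mean_DS <- tab$mean_NDS <- (tab$mean_DS + tab$mean_NDS) / 2
    tab$sd_DS <- tab$sd_NDS <- sqrt((tab$sd_DS^2 + tab$sd_NDS^2) / 2)
  }
  structure(list(table = tab, pairing_correlation = pairing_correlation,
                 latent_loading = latent_loading,
                 latent_vars = c("FRI", "AES", "MJS", "ACA", "PCPL")),
            class = "effect_spec")
}

# invariant bounds used to truncate draws (kept inside the generator's
# geometric feasibility envelope)
param_bounds <- function() {
  b <- list(
    MxH = c(35, 70), RH = c(30, 70), FRI = c(60, 120), LRI = c(60, 120),
    BL = c(55, 95),
    APCP = c(2, 25), TCP = c(42, 65), VCP = c(1, 20),
    SJS = c(0.4, 6), AJS = c(0.4, 6), PJS = c(0.4, 6), MJS = c(0.4, 6),
    LJS = c(0.4, 6), ACA = c(3, 60),
    AES = c(18, 78), PES = c(18, 78), MES = c(18, 78), LES = c(18, 78),
    OCPL = c(6, 30), PCPL = c(3, 18), SCI = c(15, 70), TCI = c(-15, 15),
    BA = c(2, 40), NCPL = c(2.5, 16), NIPL = c(2, 14))
  b
}

truncnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:50) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

# draw one subject's true parameter values: list with per-side vectors and
# the asymmetry criteria values
draw_subject <- function(spec) {
  tab <- spec$table
  rho <- spec$pairing_correlation
  lam <- spec$latent_loading
  u <- stats::rnorm(1)                  # latent deviated-side factor
  bounds <- param_bounds()
  np <- nrow(tab)
  is_lat <- lam > 0 & tab$param %in% spec$latent_vars
  zc <- stats::rnorm(np)
  zc[is_lat] <- lam * u + sqrt(1 - lam^2) * zc[is_lat]
  zn <- rho * zc + sqrt(1 - rho^2) * stats::rnorm(np)
  lo <- vapply(tab$param, function(p) bounds[[p]][1], numeric(1))
  hi <- vapply(tab$param, function(p) bounds[[p]][2], numeric(1))
  ds <- tab$mean_DS + tab$sd_DS * zc
  nds <- tab$mean_NDS + tab$sd_NDS * zn
  redraw <- function(v, mean, sd) {
    for (r in 1:50) {
      bad <- which(v < lo | v > hi)
      if (!length(bad)) return(v)
      v[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    }
    pmin(pmax(v, lo), hi)
  }
  ds <- stats::setNames(redraw(ds, tab$mean_DS, tab$sd_DS), tab$param)
  nds <- stats::setNames(redraw(nds, tab$mean_NDS, tab$sd_NDS), tab$param)
  side <- sample(c("left", "right"), 1)
  dev <- truncnorm1(5.5, 1.5, 3.2, 12) * (if (side == "left") 1 else -1)
  list(ds = ds, nds = nds, menton_deviation = dev, deviated_side = side,
       anb = truncnorm1(-2.5, 1.2, -7, -0.2),
       pog_nperp = truncnorm1(3, 1.5, 0.2, 8))
}

#' Generate a synthetic cohort
#'
#' Draws per-subject parameter sets from the effect specification (Gaussian
#' per-side marginals, pairing correlation, deviated-side latent factor,
#' truncated to geometric invariants) and returns the subject specifications
#' together with the ground-truth cohort table.
#'
#' @param n_subjects number of subjects.
#' @param spec `effect_spec`.
#' @param seed integer seed.
#' @return list with `subjects` (list of per-subject draws: `ds`, `nds`,
#'   `menton_deviation`, `deviated_side`, `anb`, `pog_nperp`) and `table`
#'   (ground-truth cohort table: data frame with columns `subject`,
#'   `deviated_side`, and `<var>_DS` / `<var>_NDS`).
#' @export
generate_cohort <- function(n_subjects, spec = effect_spec(), seed = 1L) {
  set.seed(as.integer(seed))
  subjects <- lapply(seq_len(n_subjects), function(i) draw_subject(spec))
  vals <- t(vapply(subjects, function(s) c(s$ds, s$nds),
                   numeric(2 * length(subjects[[1]]$ds))))
  colnames(vals) <- c(paste0(names(subjects[[1]]$ds), "_DS"),
                      paste0(names(subjects[[1]]$nds), "_NDS"))
  tab <- data.frame(subject = seq_len(n_subjects),
                    deviated_side = vapply(subjects, `[[`, "", "deviated_side"),
                    vals)
  list(subjects = subjects, table = tab)
}

#' Variable names present in a cohort table
#' @param cohort cohort table data frame.
#' @return character vector.
#' @export
cohort_variables <- function(cohort) {
  nm <- names(cohort)
  sub("_DS$", "", nm[grepl("_DS$", nm)])
}

ALL_PARAMS <- function() c(MORPHO_PARAMS, KINEMATIC_PARAMS)
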