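# shared fixtures built in code; cached per test session
.fixtures <- new.env(parent = emptyenv())

default_skull <- function(seed = 7, world_pose = FALSE) {
  key <- paste0("skull_", seed, "_", world_pose)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_skull(skull_config(), seed = seed,
                                       world_pose = world_pose)
  .fixtures[[key]]
}

default_morpho <- function() {
  if (is.null(.fixtures$morpho))
    .fixtures$morpho <- measure_morphometry(default_skull()$landmarks)
  .fixtures$morpho
}

noiseless_recordings <- function(seed = 3) {
  key <- paste0("rec0_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_recordings(default_skull()$landmarks,
                                            motion_config(marker_noise_sd = 0),
                                            seed = seed)
  .fixtures[[key]]
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_rigid_tf <- function(tmax = 30) {
  rigid3(rotation_about_axis(random_unit(), stats::runif(1, 0, 180)),
         stats::rnorm(3, 0, tmax))
}

# random truncated per-side morphometric draw within generator feasibility
random_morpho_config <- function() {
  spec <- default_morpho_spec()
  clamp <- function(v) {
    js <- c("SJS", "AJS", "PJS", "MJS", "LJS")
    v[js] <- pmax(v[js], 0.4)
    em <- c("AES", "PES", "MES", "LES")
    v[em] <- pmin(pmax(v[em], 18), 80)
    v["ACA"] <- min(max(v["ACA"], 2), 80)
    v
  }
  dsv <- stats::setNames(stats::rnorm(18, spec$mean_DS, spec$sd_DS), spec$param)
  ndv <- stats::setNames(stats::rnorm(18, spec$mean_NDS, spec$sd_NDS), spec$param)
  skull_config(menton_deviation = sample(c(-1, 1), 1) * stats::runif(1, 3.2, 9),
               ds = clamp(dsv), nds = clamp(ndv))
}
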