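# Generator profiles: the tunable ground-truth parameters of one simulated
# synapse scenario.  Built-in profiles encode the imaging conditions and
# summary statistics reported for primary CD8+ T cells, Jurkat T cells,
# WASP-knockout primary cells and CK666-treated primary cells; the
# wave-coupling probabilities and wave nucleation rates were calibrated once
# by simulation sweep so that the realized ground-truth anterograde fractions
# match the per-condition reference values (see the methods vignette).

# Per-condition parameters.  Speeds in nm/s; coupling_prob and
# diffusive_fraction are probabilities; wave_nucleation_rate in fronts/s.
.profile_table <- list(
  primary = list(
    retro_speed = 42.42, retro_speed_sd = 4.0,
    actin_flow_speed = 41.29, diffusive_fraction = 0.38,
    wave_nucleation_rate = 0.135, wave_arc = 1.2,
    coupling_prob = 0.74
  ),
  jurkat = list(
    retro_speed = 45.95, retro_speed_sd = 4.0,
    actin_flow_speed = 50.89, diffusive_fraction = 0.34,
    wave_nucleation_rate = 0, wave_arc = 1.2,
    coupling_prob = 0
  ),
  wasp_ko = list(
    retro_speed = 39.69, retro_speed_sd = 4.0,
    actin_flow_speed = 50.06, diffusive_fraction = 0.38,
    wave_nucleation_rate = 0.13, wave_arc = 1.2,
    coupling_prob = 0.12
  ),
  ck666 = list(
    retro_speed = 41.34, retro_speed_sd = 4.0,
    actin_flow_speed = 38.43, diffusive_fraction = 0.38,
    wave_nucleation_rate = 0.14, wave_arc = 1.2,
    coupling_prob = 0.75
  )
)

# Parameters shared by all conditions unless overridden.
.profile_defaults <- list(
  pixel_size = 41.6,          # nm/px
  frame_interval = 1,         # s
  n_frames = 200,
  cell_radius = 3000,         # nm
  csmac_radius = 750,         # nm
  wave_speed = 40,            # nm/s, outward front expansion
  wave_band = 600,            # nm, radial thickness of the bright band
  capture_radius = 300,       # nm, cluster-front capture distance
  jitter_sd = 9,              # nm per axis per frame, drifting clusters
  diffusive_fraction = 0.38,  # fraction of clusters without net drift
  diffusive_jitter_sd = 30,   # nm per axis per frame, diffusive clusters
  cluster_lifetime = 60,      # s, mean unbinding time
  n_clusters = 40,            # concurrent clusters
  min_separation = 500,       # nm, enforced at (re)spawn
  cluster_photon_rate = 5000, # photons/frame per cluster
  psf_sigma = 60,             # nm (SIM-scale PSF)
  background_rate = 10,       # photons/px/frame, TCR channel
  read_noise_sd = 2,          # intensity units
  n_speckles = 800,
  speckle_photon_rate = 7700, # photons/frame per speckle (mean)
  speckle_sigma = 83,         # nm
  speckle_lifetime = 12,      # s, actin speckle turnover time
  cortex_rate = 10000,        # photons/px/frame, cortical actin base
  csmac_dim = 0.3,            # cortical intensity factor inside cSMAC
  wave_amplitude = 1000,      # photons/px, wave plateau height
  wave_front_sigma = 33,      # nm, leading-edge rise width
  wave_back_sigma = 450,      # nm, trailing taper of the band
  margin = 8,                 # px image margin around the cell disc
  seed = 1
)

.profile_numeric_bounds <- function() {
  # name -> c(min, max); NA means unbounded on that side
  list(
    pixel_size = c(1e-6, NA), frame_interval = c(1e-6, NA),
    n_frames = c(2, NA), cell_radius = c(1e-6, NA),
    csmac_radius = c(0, NA), retro_speed = c(0, NA),
    retro_speed_sd = c(0, NA), actin_flow_speed = c(0, NA),
    wave_speed = c(1e-6, NA), wave_nucleation_rate = c(0, NA),
    wave_arc = c(1e-6, 2 * pi), coupling_prob = c(0, 1),
    capture_radius = c(1e-6, NA), jitter_sd = c(0, NA),
    diffusive_fraction = c(0, 1), diffusive_jitter_sd = c(0, NA),
    cluster_lifetime = c(1e-6, NA), n_clusters = c(0, NA),
    min_separation = c(0, NA), cluster_photon_rate = c(0, NA),
    psf_sigma = c(1e-6, NA), background_rate = c(0, NA),
    read_noise_sd = c(0, NA), n_speckles = c(0, NA),
    speckle_photon_rate = c(0, NA), speckle_sigma = c(1e-6, NA),
    speckle_lifetime = c(1e-6, NA),
    cortex_rate = c(0, NA), csmac_dim = c(0, 1),
    wave_amplitude = c(0, NA), wave_band = c(1e-6, NA),
    wave_front_sigma = c(1e-6, NA), wave_back_sigma = c(1e-6, NA),
    margin = c(0, NA), seed = c(NA, NA)
  )
}

#' Create a generator profile
#'
#' Returns the full parameter set of one simulated synapse scenario.
#' Built-in profiles (\code{"primary"}, \code{"jurkat"}, \code{"wasp_ko"},
#' \code{"ck666"}) encode the per-condition reference values: retrograde
#' cluster speed, actin flow speed, wavefront nucleation and the calibrated
#' cluster-wave coupling probability.  \code{"custom"} starts from the
#' primary parameter set and applies \code{overrides}.
#'
#' @param name one of \code{"primary"}, \code{"jurkat"}, \code{"wasp_ko"},
#'   \code{"ck666"}, \code{"custom"}.
#' @param overrides named list of parameter overrides (e.g.
#'   \code{list(seed = 7, n_frames = 50)}).
#' @return a \code{GeneratorProfile}: a named list of validated parameters.
#' @examples
#' p <- make_profile("primary", list(seed = 7))
#' p$retro_speed
#' @export
make_profile <- function(name, overrides = list()) {
  known <- c(names(.profile_table), "custom")
  if (!is.character(name) || length(name) != 1L || !(name %in% known))
    stop("unknown profile name: ", paste(name, collapse = ", "))
  base <- .profile_defaults
  cond <- if (name == "custom") .profile_table[["primary"]]
          else .profile_table[[name]]
  base[names(cond)] <- cond
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("overrides must be a fully named list")
    unknown <- setdiff(names(overrides), c(names(base), "name"))
    if (length(unknown))
      stop("unknown profile parameter(s): ", paste(unknown, collapse = ", "))
    base[names(overrides)] <- overrides
  }
  base$name <- name
  validate_profile(base)
}

#' Validate a generator profile
#'
#' Checks every numeric parameter against its admissible range and the
#' cross-parameter constraints (cSMAC smaller than the cell, probabilities
#' in \[0, 1\]).
#'
#' @param profile a profile list as returned by [make_profile()].
#' @return the profile, invisibly unchanged, or an error.
#' @export
validate_profile <- function(profile) {
  bounds <- .profile_numeric_bounds()
  for (nm in names(bounds)) {
    v <- profile[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("profile parameter '", nm, "' missing or not a finite number")
    b <- bounds[[nm]]
    if (!is.na(b[1]) && v < b[1])
      stop("profile parameter '", nm, "' = ", v, " below minimum ", b[1])
    if (!is.na(b[2]) && v > b[2])
      stop("profile parameter '", nm, "' = ", v, " above maximum ", b[2])
  }
  if (profile$csmac_radius >= profile$cell_radius)
    stop("csmac_radius must be smaller than cell_radius")
  profile$n_frames <- as.integer(profile$n_frames)
  profile$n_clusters <- as.integer(profile$n_clusters)
  profile$n_speckles <- as.integer(profile$n_speckles)
  class(profile) <- "GeneratorProfile"
  profile
}

#' @export
print.GeneratorProfile <- function(x, ...) {
  cat(sprintf("GeneratorProfile '%s': %d frames @ %.2f s, %.1f nm/px\n",
              x$name, x$n_frames, x$frame_interval, x$pixel_size))
  cat(sprintf("  cell R %.0f nm (cSMAC %.0f), retro %.2f nm/s, waves %.2f/s @ %.0f nm/s, coupling %.3f\n",
              x$cell_radius, x$csmac_radius, x$retro_speed,
              x$wave_nucleation_rate, x$wave_speed, x$coupling_prob))
  invisible(x)
}

# Convenience conversions (px / frame units) used by the simulator.
profile_px <- function(profile) {
  ps <- profile$pixel_size
  dt <- profile$frame_interval
  list(
    R = profile$cell_radius / ps,
    rc = profile$csmac_radius / ps,
    retro_step = profile$retro_speed * dt / ps,
    retro_step_sd = profile$retro_speed_sd * dt / ps,
    wave_step = profile$wave_speed * dt / ps,
    capture = profile$capture_radius / ps,
    jitter = profile$jitter_sd * sqrt(dt) / ps,
    diff_jitter = profile$diffusive_jitter_sd * sqrt(dt) / ps,
    min_sep = profile$min_separation / ps,
    psf = profile$psf_sigma / ps,
    speckle_sigma = profile$speckle_sigma / ps,
    band = profile$wave_band / ps,
    front_sigma = profile$wave_front_sigma / ps,
    back_sigma = profile$wave_back_sigma / ps,
    img = 2L * (ceiling(profile$cell_radius / ps) + profile$margin)
  )
}
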