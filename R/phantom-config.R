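# Configuration of the synthetic CMR phantom cohort. The defaults ARE the
# study conditions the package is validated under: 12 subjects imaged at
# baseline and 6 months, first-pass series of 50 frames at 1 s on three
# short-axis levels, and effect sizes taken from the study group statistics.

#' Phantom cohort configuration
#'
#' Collects every tunable of the synthetic-data generator: acquisition
#' timing, arterial-input-function shape, tissue impulse-response shape,
#' image geometry, noise level, and the per-metric paired effect sizes used
#' to draw virtual cohorts.
#'
#' @param seed Integer RNG seed; identical configs (including seed) produce
#'   byte-identical phantoms.
#' @param n_subjects Number of virtual subjects (>= 2 for paired analysis).
#' @param n_frames Dynamic frames per perfusion series (>= 30, matching a
#'   first-pass acquisition of 30-60 heart beats).
#' @param frame_interval_s Seconds per dynamic frame (> 0).
#' @param aif_params Gamma-variate parameters of the arterial input
#'   function: `amplitude` (signal-intensity units at the first-pass peak),
#'   `onset_s`, dimensionless `shape`, `scale_s`, plus `recirc_fraction`,
#'   `recirc_delay_s` and `recirc_broadening` for the delayed, scaled
#'   recirculation copy.
#' @param fermi_shape Tissue impulse-response shape: width `k_s`, shoulder
#'   `w_s` and delay `delay_s`, all in seconds.
#' @param noise_sd Additive Gaussian image noise SD in signal-intensity
#'   units (>= 0; 0 gives noise-free closure phantoms).
#' @param grid_shape Rows and columns per slice.
#' @param n_slices Short-axis levels (3: basal, mid, apical).
#' @param voxel_volume_ml Voxel volume in mL.
#' @param baseline_si Pre-contrast tissue signal intensity.
#' @param n_baseline_frames Pre-contrast frames used for baseline
#'   correction (default 3).
#' @param rho Within-subject correlation between baseline and follow-up
#'   draws of each metric (Gaussian copula; default 0.7).
#' @param effect_sizes Named list of per-metric `(mean, sd)` pairs at
#'   baseline and follow-up; see [default_effect_sizes()].
#' @return A validated list of class `"phantom_config"`.
#' @export
phantom_config <- function(seed = 1L,
                           n_subjects = 12L,
                           n_frames = 50L,
                           frame_interval_s = 1,
                           aif_params = list(amplitude = 80, onset_s = 8,
                                             shape = 3, scale_s = 1.5,
                                             recirc_fraction = 0.15,
                                             recirc_delay_s = 20,
                                             recirc_broadening = 1),
                           fermi_shape = list(k_s = 2, w_s = 8, delay_s = 1),
                           noise_sd = 0,
                           grid_shape = c(64L, 64L),
                           n_slices = 3L,
                           voxel_volume_ml = 0.023,
                           baseline_si = 100,
                           n_baseline_frames = 3L,
                           rho = 0.7,
                           effect_sizes = default_effect_sizes()) {
  cfg <- list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
              n_frames = as.integer(n_frames),
              frame_interval_s = frame_interval_s, aif_params = aif_params,
              fermi_shape = fermi_shape, noise_sd = noise_sd,
              grid_shape = as.integer(grid_shape),
              n_slices = as.integer(n_slices),
              voxel_volume_ml = voxel_volume_ml, baseline_si = baseline_si,
              n_baseline_frames = as.integer(n_baseline_frames), rho = rho,
              effect_sizes = effect_sizes)
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (cfg$n_frames < 30L)
    cmr_invalid("n_frames must be >= 30 (first-pass series covers 30-60 beats)")
  if (!is.finite(cfg$frame_interval_s) || cfg$frame_interval_s <= 0)
    cmr_invalid("frame_interval_s must be > 0")
  if (cfg$noise_sd < 0) cmr_invalid("noise_sd must be >= 0")
  ap <- cfg$aif_params
  needed <- c("amplitude", "onset_s", "shape", "scale_s",
              "recirc_fraction", "recirc_delay_s")
  if (!all(needed %in% names(ap)))
    cmr_invalid("aif_params missing fields: ",
                paste(setdiff(needed, names(ap)), collapse = ", "))
  if (ap$shape <= 0 || ap$scale_s <= 0)
    cmr_invalid("gamma-variate shape and scale must be > 0")
  for (m in names(cfg$effect_sizes)) {
    es <- cfg$effect_sizes[[m]]
    if (es$baseline[2L] < 0 || es$followup[2L] < 0)
      cmr_invalid("effect-size SDs must be >= 0 (metric ", m, ")")
  }
  if (length(cfg$grid_shape) != 2L || any(cfg$grid_shape < 16L))
    cmr_invalid("grid_shape must be two dimensions of at least 16 voxels")
  invisible(cfg)
}

#' Default paired effect sizes for the virtual cohort
#'
#' Per-metric `(mean, sd)` at baseline and 6-month follow-up for the
#' quantities the pipeline measures: ejection fraction, end-diastolic
#' volume, indexed LV mass, targeted-region wall thickening, regional
#' myocardial blood flow at rest and under adenosine stress, myocardial
#' perfusion reserve, and scar-burden percentages. Flow and MPR values
#' reflect an ischaemic targeted territory (low reserve at baseline,
#' improving at follow-up) against a near-normal non-targeted territory.
#'
#' @return Named list; each element has numeric `baseline` and `followup`
#'   entries of the form `c(mean, sd)`.
#' @export
default_effect_sizes <- function() {
  es <- function(b, f) list(baseline = b, followup = f)
  list(
    ef_pct = es(c(51, 10), c(56, 9)),
    edv_ml = es(c(150, 33), c(146, 30)),
    mass_g_per_m2 = es(c(99, 28), c(95.6, 28.5)),
    thickening_pct_targeted = es(c(48.1, 10.2), c(53.4, 8.6)),
    mbf_rest_targeted = es(c(0.67, 0.17), c(0.75, 0.3)),
    mbf_stress_targeted = es(c(0.83, 0.16), c(1.12, 0.5)),
    mbf_rest_nontargeted = es(c(0.97, 0.9), c(1.01, 0.5)),
    mbf_stress_nontargeted = es(c(2.01, 0.7), c(2.3, 0.7)),
    mpr_targeted = es(c(1.2, 0.3), c(1.5, 0.4)),
    mpr_nontargeted = es(c(2.1, 0.6), c(2.3, 0.6)),
    pct_mde_total = es(c(24, 12), c(18.5, 10)),
    pct_mde_peri = es(c(40, 15), c(24.8, 12))
  )
}
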