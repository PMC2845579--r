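# Voxel-level first-pass perfusion phantom: an annular myocardium on each
# of three short-axis slices, sector-wise tissue curves generated from
# per-segment true MBF values, and an LV blood pool on the basal slice
# carrying the arterial input function. Signal-intensity level only — no
# MR physics.

#' Generate a phantom first-pass perfusion study
#'
#' Builds a 4D dynamic series (rows x cols x slices x frames). Every
#' myocardial voxel carries `baseline_si` plus the noise-free tissue curve
#' of its segment (AIF convolved with the Fermi impulse response at that
#' segment's true MBF); blood-pool voxels carry `baseline_si` plus the AIF.
#' Gaussian noise of SD `config$noise_sd` is added last. Uses the current
#' RNG state; seed at the call site (or via [generate_cohort()]) for
#' reproducibility.
#'
#' @param config A [phantom_config()].
#' @param mbf_segments Numeric vector of true MBF (mL/min/g), one value per
#'   segment of `model` (length 16 for the default model).
#' @param state `"rest"` or `"stress"`.
#' @param model Segment model from [segment_model()].
#' @return A `perfusion_study` list: `image` (4D array), `frame_times`,
#'   `myo_mask` (3D logical), `blood_mask` (3D logical, basal slice only),
#'   `state`, `model`, `n_baseline_frames`, and a `truth` element with the
#'   planted MBF values and the noise-free AIF.
#' @export
generate_perfusion_study <- function(config, mbf_segments,
                                     state = c("rest", "stress"),
                                     model = segment_model()) {
  state <- match.arg(state)
  validate_phantom_config(config)
  if (any(mbf_segments < 0)) cmr_invalid("true MBF values must be >= 0")
  if (length(mbf_segments) != nrow(model))
    cmr_invalid("mbf_segments must have one value per model segment")
  nr <- config$grid_shape[1L]; nc <- config$grid_shape[2L]
  ns <- config$n_slices; nf <- config$n_frames
  geom <- phantom_annulus_geometry(nr, nc)
  aif <- generate_aif(config)

  myo <- array(FALSE, c(nr, nc, ns))
  blood <- array(FALSE, c(nr, nc, ns))
  img <- array(config$baseline_si, c(nr, nc, ns, nf))
  rr <- matrix(rep(seq_len(nr), nc), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rad <- sqrt((rr - geom$center[1L])^2 + (cc - geom$center[2L])^2)
  annulus <- rad >= geom$r_endo & rad <= geom$r_epi
  pool <- rad <= geom$r_pool

  for (s in seq_len(ns)) myo[, , s] <- annulus
  blood[, , 1L] <- pool  # AIF measured in the basal LV blood pool

  # Per-segment noise-free tissue curves
  seg_ids <- sort(unique(model$segment_id))
  curves <- vapply(seg_ids, function(id) {
    generate_tissue_curve(aif, mbf_segments[id], config$fermi_shape,
                          noise_sd = 0)
  }, numeric(nf))

  for (s in seq_len(ns)) {
    sec <- assign_sectors(myo[, , s], model, s)
    for (id in model$segment_id[model$slice_index == s]) {
      vox <- which(!is.na(sec) & sec == id)
      if (length(vox) == 0L) next
      slab <- img[, , s, ]                 # rows x cols x frames
      slab_m <- matrix(slab, nr * nc, nf)
      slab_m[vox, ] <- slab_m[vox, , drop = FALSE] +
        matrix(curves[, id], length(vox), nf, byrow = TRUE)
      img[, , s, ] <- array(slab_m, c(nr, nc, nf))
    }
  }
  pool_vox <- which(pool)
  slab_m <- matrix(img[, , 1L, ], nr * nc, nf)
  slab_m[pool_vox, ] <- slab_m[pool_vox, , drop = FALSE] +
    matrix(aif$signal, length(pool_vox), nf, byrow = TRUE)
  img[, , 1L, ] <- array(slab_m, c(nr, nc, nf))

  if (config$noise_sd > 0)
    img <- img + array(rnorm(length(img), sd = config$noise_sd), dim(img))

  structure(list(image = img, frame_times = aif$time, myo_mask = myo,
                 blood_mask = blood, state = state, model = model,
                 n_baseline_frames = config$n_baseline_frames,
                 truth = list(mbf_segments = mbf_segments,
                              aif = aif$signal,
                              fermi_shape = config$fermi_shape)),
            class = "perfusion_study")
}

# Shared annulus geometry: radii scale with the grid so masks stay inside
# bounds at any resolution.
phantom_annulus_geometry <- function(nr, nc) {
  m <- min(nr, nc)
  list(center = c((nr + 1) / 2, (nc + 1) / 2),
       r_endo = 0.18 * m, r_epi = 0.32 * m, r_pool = 0.13 * m)
}
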