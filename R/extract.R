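# Signal-intensity curve extraction: per-frame means over the LV blood
# pool (arterial input function) and over each myocardial sector (tissue
# curves), baseline-corrected by the mean of the pre-contrast frames and
# resampled to a uniform time grid when frame timing jitters.

#' Extract the AIF and per-segment tissue curves from a perfusion study
#'
#' Each curve is the mean signal intensity over its mask (blood pool or
#' myocardial sector) at every frame, minus the mean of that curve over the
#' first `n_baseline_frames` pre-contrast frames. Segments whose sector is
#' empty after masking are excluded with a warning (never silently zero).
#' If frame intervals vary by more than 1% the curves are linearly
#' resampled to a uniform grid.
#'
#' @param study A `perfusion_study` (see [generate_perfusion_study()] or
#'   [read_perfusion_study()]).
#' @return List with `aif` (numeric), `tissue` (frames x segments matrix,
#'   columns named by segment id), `time` (uniform, s), `dt` (s),
#'   `excluded` (integer vector of dropped segment ids) and `model`.
#' @export
extract_curves <- function(study) {
  img <- study$image
  dm <- dim(img)
  if (length(dm) != 4L) cmr_invalid("perfusion image must be 4D")
  nf <- dm[4L]
  if (nf < 30L) cmr_invalid("perfusion series needs >= 30 frames")
  ft <- study$frame_times
  if (length(ft) != nf || any(diff(ft) <= 0))
    cmr_invalid("frame times must be strictly increasing, one per frame")
  nb <- study$n_baseline_frames %||% 3L
  if (!any(study$blood_mask)) cmr_invalid("blood-pool mask is empty")

  model <- study$model
  nvox_slice <- dm[1L] * dm[2L]
  frame_mat <- function(s) matrix(img[, , s, ], nvox_slice, nf)

  # AIF: mean over blood-pool voxels (any slice carrying them)
  aif_acc <- numeric(nf); aif_n <- 0L
  for (s in seq_len(dm[3L])) {
    vox <- which(study$blood_mask[, , s])
    if (length(vox) == 0L) next
    aif_acc <- aif_acc + colSums(frame_mat(s)[vox, , drop = FALSE])
    aif_n <- aif_n + length(vox)
  }
  aif <- aif_acc / aif_n

  tissue <- matrix(NA_real_, nf, nrow(model),
                   dimnames = list(NULL, model$segment_id))
  excluded <- integer(0)
  for (s in seq_len(dm[3L])) {
    sec <- assign_sectors(study$myo_mask[, , s], model, s)
    fm <- frame_mat(s)
    for (id in model$segment_id[model$slice_index == s]) {
      vox <- which(!is.na(sec) & sec == id)
      if (length(vox) == 0L) {
        warning("segment ", id, " empty after masking; excluded",
                call. = FALSE)
        excluded <- c(excluded, id)
        next
      }
      tissue[, as.character(id)] <- colMeans(fm[vox, , drop = FALSE])
    }
  }
  # Model segments living on slices beyond the stack are also excluded
  missing <- model$segment_id[model$slice_index > dm[3L]]
  excluded <- sort(unique(c(excluded, missing)))

  # Uniform-grid resampling when frame timing jitters > 1%
  d <- diff(ft)
  dt <- mean(d)
  if ((max(d) - min(d)) / dt > 0.01) {
    tu <- seq(ft[1L], ft[nf], length.out = nf)
    aif <- approx(ft, aif, xout = tu)$y
    tissue <- apply(tissue, 2L, function(y) {
      if (all(is.na(y))) y else approx(ft, y, xout = tu)$y
    })
    ft <- tu
    dt <- ft[2L] - ft[1L]
  }

  baseline_correct <- function(y) y - mean(y[seq_len(nb)])
  aif <- baseline_correct(aif)
  keep <- setdiff(model$segment_id, excluded)
  tissue <- tissue[, as.character(keep), drop = FALSE]
  tissue <- apply(tissue, 2L, baseline_correct)

  list(aif = aif, tissue = tissue, time = ft, dt = dt,
       excluded = excluded, model = model)
}
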