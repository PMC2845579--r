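# Remote-referenced SD-threshold scar quantification. Per slice, the
# remote ROI supplies a reference mean and sample SD; myocardial voxels
# strictly above mean + 2 SD form the total enhancement mask, which is
# partitioned into a strongly enhanced core (> mean + 3 SD) and the
# peri-infarct zone (2-3 SD band, closed on top). Masses follow from voxel
# counts, voxel volume and the 1.05 g/mL tissue density.

#' Construct an LGE study object
#'
#' @param image 3D numeric array (rows x cols x slices) of late-enhancement
#'   signal intensities (a single slice may be passed as a matrix).
#' @param myo_mask Logical array, same shape: myocardium.
#' @param remote_mask Logical array, same shape: remote reference ROI; must
#'   be a subset of the myocardium and non-empty on every analysed slice.
#' @param voxel_volume_ml Voxel volume (mL).
#' @param density_g_per_ml Myocardial tissue density (default 1.05 g/mL).
#' @return List of class `"lge_study"`.
#' @export
lge_study <- function(image, myo_mask, remote_mask, voxel_volume_ml,
                      density_g_per_ml = 1.05) {
  as3d <- function(x) if (length(dim(x)) == 2L) array(x, c(dim(x), 1L)) else x
  image <- as3d(image); myo_mask <- as3d(myo_mask)
  remote_mask <- as3d(remote_mask)
  if (!identical(dim(image), dim(myo_mask)) ||
      !identical(dim(image), dim(remote_mask)))
    cmr_invalid("image and mask dimensions differ")
  if (any(remote_mask & !myo_mask))
    cmr_invalid("remote ROI must lie inside the myocardium mask")
  if (voxel_volume_ml <= 0) cmr_invalid("voxel_volume_ml must be > 0")
  structure(list(image = image, myo_mask = myo_mask,
                 remote_mask = remote_mask,
                 voxel_volume_ml = voxel_volume_ml,
                 density_g_per_ml = density_g_per_ml),
            class = "lge_study")
}

#' Remote-region reference statistics for one slice
#'
#' Mean and sample SD (denominator n - 1) of the remote-ROI voxel
#' intensities on the given slice. A remote ROI smaller than 8 voxels
#' triggers an unreliable-reference warning; an empty one is an error.
#'
#' @param study An [lge_study()].
#' @param slice_index Slice number (1-based).
#' @return Named numeric vector `c(mu, sigma)`.
#' @examples
#' # two remote voxels at 40 and 60 -> mu 50, sigma 14.14
#' @export
remote_stats <- function(study, slice_index) {
  v <- study$image[, , slice_index][study$remote_mask[, , slice_index]]
  if (length(v) == 0L)
    cmr_compute_error("remote ROI empty on slice ", slice_index)
  if (length(v) < 8L)
    warning("remote ROI has only ", length(v),
            " voxels on slice ", slice_index,
            "; reference statistics may be unreliable", call. = FALSE)
  sigma <- if (length(v) > 1L) sd(v) else 0
  c(mu = mean(v), sigma = sigma)
}

#' Partition an LGE study into core and peri-infarct enhancement
#'
#' Per slice, with remote reference `(mu, sigma)`: total enhancement is
#' every myocardial voxel with intensity strictly above `mu + sd_total *
#' sigma`; core is strictly above `mu + sd_core * sigma`; peri-infarct is
#' the half-open band in between (a voxel exactly at the core threshold
#' stays peri-infarct). With a degenerate reference (`sigma = 0`) both
#' thresholds collapse to `mu`, so every voxel strictly above the remote
#' mean is core and the peri zone is empty — the limiting behaviour of
#' both rules. Masses are voxel count x voxel volume x tissue density.
#'
#' @param study An [lge_study()].
#' @param sd_total,sd_core SD multipliers of the total and core thresholds
#'   (defaults 2 and 3; must satisfy `0 < sd_total < sd_core`).
#' @return List of class `"infarct_partition"`: logical arrays `total`,
#'   `core`, `peri`; masses `mde_total_g`, `mde_core_g`, `mde_peri_g`;
#'   `pct_core_of_total`, `pct_peri_of_total` (percentages of total
#'   enhancement mass, `NA` when total is empty); per-slice `remote` data
#'   frame (`slice`, `mu`, `sigma`); `lv_myo_mass_g` (mass of the stack's
#'   myocardium mask).
#' @export
partition_infarct <- function(study, sd_total = 2, sd_core = 3) {
  if (!(sd_total > 0 && sd_core > sd_total))
    cmr_invalid("SD multipliers must satisfy 0 < sd_total < sd_core")
  if (is.null(study$myo_mask)) cmr_invalid("myocardium mask missing")
  dm <- dim(study$image)
  total <- core <- array(FALSE, dm)
  remote <- data.frame(slice = seq_len(dm[3L]), mu = NA_real_,
                       sigma = NA_real_)
  for (s in seq_len(dm[3L])) {
    st <- remote_stats(study, s)
    remote$mu[s] <- st[["mu"]]; remote$sigma[s] <- st[["sigma"]]
    img <- study$image[, , s]
    myo <- study$myo_mask[, , s]
    total[, , s] <- myo & img > st[["mu"]] + sd_total * st[["sigma"]]
    core[, , s] <- myo & img > st[["mu"]] + sd_core * st[["sigma"]]
  }
  peri <- total & !core
  vox_mass <- study$voxel_volume_ml * study$density_g_per_ml
  n_total <- sum(total)
  structure(list(
    total = total, core = core, peri = peri,
    mde_total_g = n_total * vox_mass,
    mde_core_g = sum(core) * vox_mass,
    mde_peri_g = sum(peri) * vox_mass,
    pct_core_of_total = if (n_total > 0) 100 * sum(core) / n_total else NA_real_,
    pct_peri_of_total = if (n_total > 0) 100 * sum(peri) / n_total else NA_real_,
    remote = remote,
    lv_myo_mass_g = sum(study$myo_mask) * vox_mass,
    sd_total = sd_total, sd_core = sd_core),
    class = "infarct_partition")
}

#' Total enhancement mass as a percentage of LV mass
#'
#' @param partition An [partition_infarct()] result.
#' @param lv_mass_g LV myocardial mass (g), > 0; defaults to the mass of
#'   the study's own myocardium mask.
#' @return `100 * total enhancement mass / LV mass`.
#' @export
pct_infarct_of_lv <- function(partition, lv_mass_g = NULL) {
  lv_mass_g <- lv_mass_g %||% partition$lv_myo_mass_g
  if (!is.finite(lv_mass_g) || lv_mass_g <= 0)
    cmr_invalid("lv_mass_g must be > 0")
  100 * partition$mde_total_g / lv_mass_g
}

# Class boundaries closed on the left: a sector at exactly 50% (or 75%)
# transmurality falls in the higher class.
classify_transmurality <- function(pct) {
  ifelse(pct < 50, "<50%", ifelse(pct < 75, "50-75%", ">75%"))
}

#' Transmural extent of enhancement per angular sector
#'
#' Casts radial rays from the endocardial centroid through the wall. For
#' each ray the wall chord runs from the endocardial to the epicardial
#' contour crossing; the transmural fraction is the proportion of sample
#' points along that chord falling in the total-enhancement mask. Sector
#' transmurality is the mean ray fraction, classified as `<50%`, `50-75%`
#' or `>75%` (boundaries closed on the left, so exactly 50% lands in the
#' middle class); the per-study class is the maximum sector class.
#'
#' @param partition An [partition_infarct()] result.
#' @param endo,epi Contour polygons in voxel coordinates `(x = col,
#'   y = row)` for the analysed slice.
#' @param slice_index Slice carrying the contours (default 1).
#' @param n_sectors Number of equiangular sectors (default 6).
#' @param rays_per_sector Rays cast per sector (default 12).
#' @return List with `sectors` (data frame: `sector`, `transmurality_pct`,
#'   `class`) and `study_class` (maximum sector class). Sectors with a
#'   degenerate wall (epicardial radius not beyond endocardial) are skipped
#'   with a warning and return `NA`.
#' @export
transmural_extent <- function(partition, endo, epi, slice_index = 1L,
                              n_sectors = 6L, rays_per_sector = 12L) {
  total <- partition$total[, , slice_index]
  center <- c(mean(endo[, 1L]), mean(endo[, 2L]))
  sector_pct <- rep(NA_real_, n_sectors)
  width <- 360 / n_sectors
  for (k in seq_len(n_sectors)) {
    angles <- (k - 1L) * width +
      width * (seq_len(rays_per_sector) - 0.5) / rays_per_sector
    fracs <- numeric(0)
    for (th in angles) {
      r_en <- ray_polygon_radius(endo, center, th)
      r_ep <- ray_polygon_radius(epi, center, th)
      if (is.na(r_en) || is.na(r_ep) || r_ep <= r_en + 1e-6) next
      rs <- seq(r_en, r_ep, by = 0.25)
      px <- center[1L] + rs * cos(th * pi / 180)
      py <- center[2L] + rs * sin(th * pi / 180)
      rowi <- pmin(pmax(round(py), 1L), nrow(total))
      coli <- pmin(pmax(round(px), 1L), ncol(total))
      fracs <- c(fracs, mean(total[cbind(rowi, coli)]))
    }
    if (length(fracs) == 0L) {
      warning("sector ", k, ": degenerate wall, skipped", call. = FALSE)
      next
    }
    sector_pct[k] <- 100 * mean(fracs)
  }
  cls <- classify_transmurality(sector_pct)
  lev <- c("<50%", "50-75%", ">75%")
  valid <- cls[!is.na(sector_pct)]
  study_class <- if (length(valid)) lev[max(match(valid, lev))] else NA_character_
  list(sectors = data.frame(sector = seq_len(n_sectors),
                            transmurality_pct = sector_pct,
                            class = ifelse(is.na(sector_pct), NA, cls)),
       study_class = study_class)
}
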