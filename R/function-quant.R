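# Planimetric ventricular function: Simpson-rule volumes from per-slice
# contour areas, ejection fraction, LV mass via the 1.05 g/mL tissue
# density, and segmental wall thickness / thickening from radial rays cast
# from the endocardial centroid.

phase_key <- function(phase, surface) {
  paste0(surface, "_", tolower(phase))
}

#' LV volume by slice-summation planimetry
#'
#' Simpson summation: the shoelace area of the chosen contour on every
#' slice times the slice interval (thickness + gap), summed over slices.
#' Contours are polygons in mm; volumes are returned in mL.
#'
#' @param contours A `contour_set`: list with `slices` (each holding
#'   `endo_ed`, `epi_ed`, `endo_es`, `epi_es` polygons),
#'   `slice_thickness_mm`, `slice_gap_mm`. See [generate_contour_set()].
#' @param phase `"ED"` or `"ES"`.
#' @param surface `"endo"` or `"epi"`.
#' @param min_area_cm2 Basal-slice inclusion cutoff: slices whose contour
#'   area falls below this (default 1 cm2) are excluded.
#' @return Volume in mL.
#' @examples
#' cs <- generate_contour_set(edv_ml = 150, esv_ml = 73.5)
#' volume_from_contours(cs, "ED")  # ~150
#' @export
volume_from_contours <- function(contours, phase = c("ED", "ES"),
                                 surface = c("endo", "epi"),
                                 min_area_cm2 = 1) {
  phase <- match.arg(phase); surface <- match.arg(surface)
  if (length(contours$slices) == 0L)
    cmr_invalid("contour set has no slices")
  key <- phase_key(phase, surface)
  dz <- contours$slice_thickness_mm + (contours$slice_gap_mm %||% 0)
  vol_mm3 <- 0
  used <- 0L
  for (sl in contours$slices) {
    poly <- sl[[key]]
    if (is.null(poly)) next
    if (polygon_self_intersects(poly))
      cmr_invalid("self-intersecting ", key, " contour")
    a <- polygon_area(poly)
    if (a / 100 <= min_area_cm2 && identical(sl$basal %||% FALSE, TRUE)) next
    vol_mm3 <- vol_mm3 + a * dz
    used <- used + 1L
  }
  if (used == 0L) cmr_invalid("no usable ", key, " contours")
  vol_mm3 / 1000
}

#' Ejection fraction
#'
#' @param edv,esv End-diastolic and end-systolic volumes (mL); `edv` > 0.
#' @return `100 * (edv - esv) / edv` (percent).
#' @examples
#' ejection_fraction(150, 73.5)  # 51
#' @export
ejection_fraction <- function(edv, esv) {
  if (any(!is.finite(edv)) || any(edv <= 0))
    cmr_invalid("edv must be > 0")
  100 * (edv - esv) / edv
}

#' LV mass from end-diastolic epicardial and endocardial volumes
#'
#' `(epi - endo) x 1.05 g/mL`, the myocardial shell volume times tissue
#' density.
#'
#' @param epi_volume_ed,endo_volume_ed End-diastolic volumes (mL) inside
#'   the epicardial and endocardial contours; `epi > endo` required.
#' @param density_g_per_ml Tissue density (default 1.05).
#' @return Mass in g.
#' @examples
#' lv_mass(200, 100)  # 105
#' @export
lv_mass <- function(epi_volume_ed, endo_volume_ed, density_g_per_ml = 1.05) {
  if (any(epi_volume_ed <= endo_volume_ed))
    cmr_invalid("epicardial volume must exceed endocardial volume")
  (epi_volume_ed - endo_volume_ed) * density_g_per_ml
}

#' Sector wall thickness by radial rays
#'
#' Casts rays from the endocardial centroid; per ray the thickness is the
#' distance between the endocardial and epicardial contour crossings.
#' Sector thickness is the mean over its rays.
#'
#' @param endo,epi Contour polygons (mm).
#' @param n_sectors Number of equiangular sectors (default 6).
#' @param rays_per_sector Rays per sector (minimum resolution 36 rays total
#'   is enforced).
#' @return Numeric vector of sector mean thicknesses (mm); `NA` for
#'   degenerate sectors.
#' @export
measure_wall_thickness <- function(endo, epi, n_sectors = 6L,
                                   rays_per_sector = 12L) {
  rays_per_sector <- max(rays_per_sector,
                         ceiling(36 / n_sectors))
  center <- c(mean(endo[, 1L]), mean(endo[, 2L]))
  width <- 360 / n_sectors
  vapply(seq_len(n_sectors), function(k) {
    angles <- (k - 1L) * width +
      width * (seq_len(rays_per_sector) - 0.5) / rays_per_sector
    th <- vapply(angles, function(a) {
      r_en <- ray_polygon_radius(endo, center, a)
      r_ep <- ray_polygon_radius(epi, center, a)
      if (is.na(r_en) || is.na(r_ep)) return(NA_real_)
      r_ep - r_en
    }, numeric(1L))
    th <- th[is.finite(th) & th > 0]
    if (length(th) == 0L) NA_real_ else mean(th)
  }, numeric(1L))
}

#' Percent systolic wall thickening
#'
#' `100 * (ES thickness - ED thickness) / ED thickness`, per segment.
#' Segments with non-positive end-diastolic thickness are excluded (`NA`).
#'
#' @param ed_thickness_mm,es_thickness_mm Wall thickness (mm) at
#'   end-diastole and end-systole; vectors are paired elementwise.
#' @return Percent thickening per segment.
#' @examples
#' wall_thickening(10, 14.81)  # 48.1
#' @export
wall_thickening <- function(ed_thickness_mm, es_thickness_mm) {
  out <- 100 * (es_thickness_mm - ed_thickness_mm) / ed_thickness_mm
  out[!is.finite(ed_thickness_mm) | ed_thickness_mm <= 0] <- NA_real_
  out
}

#' Full ventricular-function quantification of a contour set
#'
#' Planimetric EDV / ESV, ejection fraction, LV mass and per-sector percent
#' wall thickening (thickness measured on the mid-stack slice).
#'
#' @param contours A `contour_set`.
#' @param n_sectors Sectors for the thickening analysis (default 6).
#' @return List of class `"ventricular_function"`: `edv_ml`, `esv_ml`,
#'   `ef_pct`, `mass_g`, `thickening_pct` (per sector).
#' @export
quantify_function <- function(contours, n_sectors = 6L) {
  edv <- volume_from_contours(contours, "ED", "endo")
  esv <- volume_from_contours(contours, "ES", "endo")
  epi_ed <- volume_from_contours(contours, "ED", "epi")
  mid <- contours$slices[[ceiling(length(contours$slices) / 2)]]
  t_ed <- measure_wall_thickness(mid$endo_ed, mid$epi_ed, n_sectors)
  t_es <- measure_wall_thickness(mid$endo_es, mid$epi_es, n_sectors)
  structure(list(edv_ml = edv, esv_ml = esv,
                 ef_pct = ejection_fraction(edv, esv),
                 mass_g = lv_mass(epi_ed, edv),
                 thickening_pct = wall_thickening(t_ed, t_es)),
            class = "ventricular_function")
}
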