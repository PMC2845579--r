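# Cylindrical contour-set phantom with analytically known volumes, mass and
# wall thickening, used to exercise the planimetry and wall-thickness code.

#' Generate a contour-set phantom with known ventricular function
#'
#' Builds a stack of circular endocardial / epicardial contours (a cylinder
#' model) whose planimetric EDV, ESV, mass and percent wall thickening
#' equal the requested targets analytically. Endocardial radii follow from
#' the volumes; the end-diastolic wall thickness follows from the mass via
#' the 1.05 g/mL tissue density; the end-systolic thickness from the
#' thickening target.
#'
#' @param edv_ml,esv_ml Target end-diastolic / end-systolic volumes (mL).
#' @param mass_g Target LV mass (g).
#' @param thickening_pct Target percent systolic wall thickening.
#' @param n_slices Number of short-axis slices (default 8).
#' @param slice_thickness_mm,slice_gap_mm Slice geometry (mm).
#' @param n_vertices Vertices per circular contour polygon.
#' @return A `contour_set` list: per-slice `endo_ed`, `epi_ed`, `endo_es`,
#'   `epi_es` polygons in mm coordinates, slice geometry, and a `truth`
#'   element with the analytic EDV/ESV/EF/mass and ED/ES wall thickness.
#' @export
generate_contour_set <- function(edv_ml = 150, esv_ml = 73.5, mass_g = 180,
                                 thickening_pct = 48.1, n_slices = 8L,
                                 slice_thickness_mm = 8, slice_gap_mm = 0,
                                 n_vertices = 360L) {
  if (edv_ml <= 0 || esv_ml <= 0 || esv_ml > edv_ml)
    cmr_invalid("need 0 < esv_ml <= edv_ml")
  if (mass_g <= 0) cmr_invalid("mass_g must be > 0")
  dz <- slice_thickness_mm + slice_gap_mm
  height <- n_slices * dz
  r_endo_ed <- sqrt(edv_ml * 1000 / (pi * height))
  r_endo_es <- sqrt(esv_ml * 1000 / (pi * height))
  # mass = 1.05 * pi * ((r + t)^2 - r^2) * height / 1000
  shell_area <- mass_g * 1000 / (1.05 * height)
  r_epi_ed <- sqrt(shell_area / pi + r_endo_ed^2)
  t_ed <- r_epi_ed - r_endo_ed
  t_es <- t_ed * (1 + thickening_pct / 100)
  r_epi_es <- r_endo_es + t_es
  center <- c(0, 0)
  slices <- lapply(seq_len(n_slices), function(s) {
    list(endo_ed = circle_polygon(center, r_endo_ed, n_vertices),
         epi_ed = circle_polygon(center, r_epi_ed, n_vertices),
         endo_es = circle_polygon(center, r_endo_es, n_vertices),
         epi_es = circle_polygon(center, r_epi_es, n_vertices))
  })
  structure(list(slices = slices, slice_thickness_mm = slice_thickness_mm,
                 slice_gap_mm = slice_gap_mm,
                 truth = list(edv_ml = edv_ml, esv_ml = esv_ml,
                              ef_pct = 100 * (edv_ml - esv_ml) / edv_ml,
                              mass_g = mass_g, ed_thickness_mm = t_ed,
                              es_thickness_mm = t_es,
                              thickening_pct = thickening_pct)),
            class = "contour_set")
}
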