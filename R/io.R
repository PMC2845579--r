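# Readers and writers. Volumetric images travel as single-file NIfTI
# (4D per perfusion state, 3D per LGE study) with a JSON sidecar carrying
# frame timing, voxel volume and mask-label semantics; masks as integer
# label maps; contours as JSON; cohort tables and results as UTF-8 CSV;
# configuration as YAML.

# Perfusion label map codes
LBL_MYO <- 1L
LBL_BLOOD <- 2L
# LGE label map codes: 1 = myocardium, 2 = remote ROI (remote is also myo)
LBL_REMOTE <- 2L

#' Write a perfusion study to NIfTI + sidecar
#'
#' Writes `<prefix>.nii` (4D series), `<prefix>_labels.nii` (3D integer
#' label map: 1 myocardium, 2 LV blood pool) and `<prefix>.json` (frame
#' times, state, baseline-frame count, targeted segment ids).
#'
#' @param study A `perfusion_study`.
#' @param prefix Output path prefix (no extension).
#' @return Invisibly, the three file paths.
#' @export
write_perfusion_study <- function(study, prefix) {
  img_path <- paste0(prefix, ".nii")
  lbl_path <- paste0(prefix, "_labels.nii")
  json_path <- paste0(prefix, ".json")
  RNifti::writeNifti(RNifti::asNifti(study$image), img_path)
  labels <- array(0L, dim(study$myo_mask))
  labels[study$myo_mask] <- LBL_MYO
  labels[study$blood_mask] <- LBL_BLOOD
  RNifti::writeNifti(RNifti::asNifti(labels), lbl_path)
  model <- study$model
  jsonlite::write_json(list(
    frame_times_s = study$frame_times,
    state = study$state,
    n_baseline_frames = study$n_baseline_frames,
    targeted_segments = model$segment_id[model$label == "targeted"],
    origin_deg = attr(model, "origin_deg") %||% 90
  ), json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(img_path, lbl_path, json_path))
}

#' Read a perfusion study written by [write_perfusion_study()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `perfusion_study` list.
#' @export
read_perfusion_study <- function(prefix) {
  img <- unclass(as.array(RNifti::readNifti(paste0(prefix, ".nii"))))
  labels <- unclass(as.array(RNifti::readNifti(paste0(prefix, "_labels.nii"))))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  model <- segment_model(targeted_segments = meta$targeted_segments,
                         origin_deg = meta$origin_deg %||% 90)
  structure(list(image = img, frame_times = meta$frame_times_s,
                 myo_mask = labels == LBL_MYO,
                 blood_mask = labels == LBL_BLOOD,
                 state = meta$state, model = model,
                 n_baseline_frames = meta$n_baseline_frames %||% 3L),
            class = "perfusion_study")
}

#' Write an LGE study to NIfTI + sidecar
#'
#' `<prefix>.nii` holds the image stack, `<prefix>_labels.nii` the integer
#' label map (1 = myocardium, 2 = remote ROI) and `<prefix>.json` the voxel
#' volume and tissue density.
#'
#' @param study An [lge_study()].
#' @param prefix Output path prefix.
#' @return Invisibly, the file paths.
#' @export
write_lge_study <- function(study, prefix) {
  img_path <- paste0(prefix, ".nii")
  lbl_path <- paste0(prefix, "_labels.nii")
  json_path <- paste0(prefix, ".json")
  RNifti::writeNifti(RNifti::asNifti(study$image), img_path)
  labels <- array(0L, dim(study$myo_mask))
  labels[study$myo_mask] <- LBL_MYO
  labels[study$remote_mask] <- LBL_REMOTE
  RNifti::writeNifti(RNifti::asNifti(labels), lbl_path)
  jsonlite::write_json(list(voxel_volume_ml = study$voxel_volume_ml,
                            density_g_per_ml = study$density_g_per_ml),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(img_path, lbl_path, json_path))
}

#' Read an LGE study written by [write_lge_study()]
#' @param prefix Path prefix used at write time.
#' @return An [lge_study()].
#' @export
read_lge_study <- function(prefix) {
  img <- unclass(as.array(RNifti::readNifti(paste0(prefix, ".nii"))))
  labels <- unclass(as.array(RNifti::readNifti(paste0(prefix, "_labels.nii"))))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  lge_study(img, labels >= LBL_MYO, labels == LBL_REMOTE,
            voxel_volume_ml = meta$voxel_volume_ml,
            density_g_per_ml = meta$density_g_per_ml %||% 1.05)
}

#' Write a contour set as JSON
#'
#' Per-slice endocardial / epicardial polygon vertex lists in mm
#' coordinates, tagged ED / ES, plus slice geometry.
#'
#' @param contours A `contour_set`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_contour_set <- function(contours, path) {
  jsonlite::write_json(list(
    slice_thickness_mm = contours$slice_thickness_mm,
    slice_gap_mm = contours$slice_gap_mm %||% 0,
    slices = lapply(contours$slices, function(sl) {
      lapply(sl[c("endo_ed", "epi_ed", "endo_es", "epi_es")],
             function(p) unname(as.matrix(p)))
    })), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a contour set written by [write_contour_set()]
#' @param path JSON path.
#' @return A `contour_set`.
#' @export
read_contour_set <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  slices <- lapply(j$slices, function(sl) {
    lapply(sl, function(poly) {
      do.call(rbind, lapply(poly, function(v) unlist(v, use.names = FALSE)))
    })
  })
  structure(list(slices = slices,
                 slice_thickness_mm = j$slice_thickness_mm,
                 slice_gap_mm = j$slice_gap_mm %||% 0),
            class = "contour_set")
}

#' Write / read a cohort table as CSV
#'
#' Long format keyed by `(subject_id, timepoint)`, UTF-8, fixed column
#' order as generated.
#'
#' @param table A cohort table data frame.
#' @param path CSV path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   the table.
#' @export
write_cohort_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- read.csv(path, fileEncoding = "UTF-8")
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Regional mean myocardial blood flows of the study cohort
#'
#' The published group mean (+/- SD) myocardial blood flow at rest and
#' under adenosine stress in the targeted and non-targeted regions at
#' baseline and 6-month follow-up, shipped as a plain-text table. These
#' values seed the phantom generator defaults and the worked examples.
#'
#' @return Data frame with `region`, `timepoint`, `state`, `mean_mbf`,
#'   `sd_mbf` (mL/min/g).
#' @export
reference_flows <- function() {
  path <- system.file("extdata", "reference_flows.csv",
                      package = "cmrquant", mustWork = TRUE)
  read.csv(path)
}

# Canonical JSON serialisation of a config list (sorted names, no
# whitespace variance) and its md5 hash, recorded in provenance output.
canonical_config_json <- function(config) {
  sort_rec <- function(x) {
    if (is.list(x) && !is.null(names(x)))
      x <- lapply(x[order(names(x))], sort_rec)
    x
  }
  jsonlite::toJSON(sort_rec(unclass(config)), auto_unbox = TRUE, digits = NA)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(canonical_config_json(config)), tmp)
  unname(tools::md5sum(tmp))
}
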