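# 16-segment short-axis model: 6 equiangular segments on the basal and mid
# slices, 4 on the apical slice. Sector angles are measured counterclockwise
# from the anterior RV insertion point; each segment maps to a coronary
# territory and to a targeted / non-targeted label.

SLICE_LEVELS <- c("basal", "mid", "apical")

#' Build a 16-segment short-axis segment model
#'
#' Six 60-degree sectors on the basal and mid ventricular slices and four
#' 90-degree sectors on the apical slice, numbered counterclockwise from the
#' anterior RV insertion. Each segment carries a coronary-territory
#' assignment (LAD / RCA / LCX) and a targeted / non-targeted label used for
#' regional aggregation of perfusion metrics.
#'
#' @param targeted_territory Coronary territory whose segments are labelled
#'   `"targeted"` (default `"RCA"`, the inferior/inferoseptal wall). Ignored
#'   when `targeted_segments` is given.
#' @param targeted_segments Optional integer vector of segment ids (1..16)
#'   labelled `"targeted"` directly.
#' @param origin_deg Angular origin of sector 1 in image coordinates
#'   (degrees counterclockwise from the +x axis; default 90, anterior wall
#'   at the top of the image).
#' @return A data frame with one row per segment: `segment_id`,
#'   `slice_level`, `slice_index`, `sector_start_deg`, `sector_end_deg`
#'   (half-open sector \[start, end)), `territory`, `label`.
#' @examples
#' m <- segment_model()
#' table(m$slice_level)
#' @export
segment_model <- function(targeted_territory = "RCA",
                          targeted_segments = NULL,
                          origin_deg = 90) {
  six <- c("anterior", "anteroseptal", "inferoseptal",
           "inferior", "inferolateral", "anterolateral")
  four <- c("anterior", "septal", "inferior", "lateral")
  terr6 <- c(anterior = "LAD", anteroseptal = "LAD", inferoseptal = "RCA",
             inferior = "RCA", inferolateral = "LCX", anterolateral = "LCX")
  terr4 <- c(anterior = "LAD", septal = "LAD", inferior = "RCA",
             lateral = "LCX")
  model <- rbind(
    data.frame(slice_level = "basal", slice_index = 1L, wall = six,
               sector_start_deg = (0:5) * 60, sector_end_deg = (1:6) * 60,
               territory = unname(terr6[six])),
    data.frame(slice_level = "mid", slice_index = 2L, wall = six,
               sector_start_deg = (0:5) * 60, sector_end_deg = (1:6) * 60,
               territory = unname(terr6[six])),
    data.frame(slice_level = "apical", slice_index = 3L, wall = four,
               sector_start_deg = (0:3) * 90, sector_end_deg = (1:4) * 90,
               territory = unname(terr4[four]))
  )
  model$segment_id <- seq_len(nrow(model))
  if (is.null(targeted_segments)) {
    if (!targeted_territory %in% model$territory)
      cmr_invalid("unknown coronary territory: ", targeted_territory)
    targeted_segments <- model$segment_id[model$territory == targeted_territory]
  }
  if (!all(targeted_segments %in% model$segment_id))
    cmr_invalid("targeted_segments must be segment ids in 1..16")
  model$label <- ifelse(model$segment_id %in% targeted_segments,
                        "targeted", "nontargeted")
  attr(model, "origin_deg") <- origin_deg
  model[, c("segment_id", "slice_level", "slice_index", "wall",
            "sector_start_deg", "sector_end_deg", "territory", "label")]
}

# Segment id for every voxel of one slice's myocardium mask (NA elsewhere).
# The sector origin and boundaries come from the model; voxel angles are
# computed about the mask centroid.
assign_sectors <- function(myo_mask, model, slice_index) {
  rows_m <- which(myo_mask, arr.ind = TRUE)
  if (nrow(rows_m) == 0L) cmr_invalid("empty myocardium mask on slice")
  center <- colMeans(rows_m)
  seg <- matrix(NA_integer_, nrow(myo_mask), ncol(myo_mask))
  ang <- voxel_angles(rows_m[, 1L], rows_m[, 2L], center,
                      attr(model, "origin_deg") %||% 90)
  sl <- model[model$slice_index == slice_index, , drop = FALSE]
  ids <- integer(nrow(rows_m))
  for (k in seq_len(nrow(sl))) {
    in_sector <- ang >= sl$sector_start_deg[k] & ang < sl$sector_end_deg[k]
    ids[in_sector] <- sl$segment_id[k]
  }
  seg[rows_m] <- ids
  seg
}
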