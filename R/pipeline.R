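# Umbrella pipeline: simulate a phantom cohort to disk, then run the
# perfusion, LGE and function stages per study, assemble the measured
# cohort table and run the paired statistics. Every output is a CSV, a
# JSON provenance record, or a NIfTI/JSON study file; re-running with an
# identical config reproduces identical outputs.

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed driving every random draw of the run.
#' @param n_subjects Virtual subjects in the simulated cohort.
#' @param sd_total,sd_core SD multipliers of the enhancement thresholds
#'   (defaults 2 and 3; must be positive and strictly ordered).
#' @param density_g_per_ml Myocardial tissue density (default 1.05).
#' @param alpha Significance level for the cohort statistics (in (0, 1)).
#' @param bsa_m2 Body surface area used to de-index LV mass when building
#'   phantom contours (default 1.8 m2).
#' @param phantom Named list of [phantom_config()] overrides (grid shape,
#'   frame count, noise SD, ...).
#' @param n_baseline_frames Pre-contrast frames for baseline correction.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_subjects = 4L,
                            sd_total = 2, sd_core = 3,
                            density_g_per_ml = 1.05, alpha = 0.05,
                            bsa_m2 = 1.8, phantom = list(),
                            n_baseline_frames = 3L) {
  if (!(sd_total > 0 && sd_core > sd_total))
    cmr_invalid("SD multipliers must be positive with sd_total < sd_core")
  if (!(alpha > 0 && alpha < 1)) cmr_invalid("alpha must be in (0, 1)")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_subjects = as.integer(n_subjects), sd_total = sd_total,
                 sd_core = sd_core, density_g_per_ml = density_g_per_ml,
                 alpha = alpha, bsa_m2 = bsa_m2, phantom = phantom,
                 n_baseline_frames = as.integer(n_baseline_frames)),
            class = "pipeline_config")
}

#' Demo-scale pipeline configuration
#'
#' The packaged demo phantom: 4 subjects, 48 x 48 grids, 40 frames at 1 s,
#' modest image noise. Small enough for an interactive run while
#' exercising every stage.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_subjects Number of subjects (default 4).
#' @return A [pipeline_config()].
#' @export
demo_pipeline_config <- function(out_dir, seed = 1L, n_subjects = 4L) {
  pipeline_config(out_dir, seed = seed, n_subjects = n_subjects,
                  phantom = list(grid_shape = c(48L, 48L), n_frames = 40L,
                                 noise_sd = 0.5))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments.
#' @param out_dir Optional override of the configured output directory.
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (is.null(y$out_dir)) cmr_invalid("config must set out_dir")
  if (!is.null(y$phantom$grid_shape))
    y$phantom$grid_shape <- as.integer(unlist(y$phantom$grid_shape))
  do.call(pipeline_config, y)
}

phantom_from_pipeline <- function(config, seed) {
  args <- config$phantom
  args$seed <- seed
  args$n_subjects <- config$n_subjects
  args$n_baseline_frames <- config$n_baseline_frames
  do.call(phantom_config, args)
}

#' Simulate a phantom cohort to disk
#'
#' Draws the ground-truth cohort table with [generate_cohort()] and writes,
#' per subject and timepoint: rest and stress perfusion studies (NIfTI +
#' sidecar), a 3-slice LGE study with a planted partition matching the
#' drawn scar percentages, and a contour set matching the drawn volumes,
#' mass and thickening. A manifest CSV indexes the files; the truth table
#' is saved alongside.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest data frame (also written to
#'   `manifest.csv`).
#' @export
simulate_cohort_studies <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pcfg <- phantom_from_pipeline(config, config$seed)
  truth <- generate_cohort(pcfg)
  write_cohort_csv(truth, file.path(config$out_dir, "cohort_truth.csv"))
  model <- segment_model()
  set.seed(config$seed + 1L)
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    rel <- paste0(tr$subject_id, "_", tr$timepoint)
    stem <- file.path(config$out_dir, rel)
    mbf_seg <- function(state) {
      tv <- tr[[paste0("mbf_", state, "_targeted")]]
      nv <- tr[[paste0("mbf_", state, "_nontargeted")]]
      ifelse(model$label == "targeted", tv, nv)
    }
    for (state in c("rest", "stress")) {
      st <- generate_perfusion_study(pcfg, mbf_seg(state), state, model)
      write_perfusion_study(st, paste0(stem, "_perf_", state))
    }
    lge <- lge_from_truth(pcfg, tr)
    write_lge_study(lge, paste0(stem, "_lge"))
    esv <- tr$edv_ml * (1 - tr$ef_pct / 100)
    cs <- generate_contour_set(edv_ml = tr$edv_ml, esv_ml = esv,
                               mass_g = tr$mass_g_per_m2 * config$bsa_m2,
                               thickening_pct = tr$thickening_pct_targeted)
    write_contour_set(cs, paste0(stem, "_contours.json"))
    # Manifest paths are relative to out_dir so a run is relocatable and
    # re-runs into any directory produce identical bytes.
    rows[[i]] <- data.frame(
      subject_id = tr$subject_id, timepoint = tr$timepoint,
      perf_rest = paste0(rel, "_perf_rest"),
      perf_stress = paste0(rel, "_perf_stress"),
      lge = paste0(rel, "_lge"),
      contours = paste0(rel, "_contours.json"))
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
            row.names = FALSE)
  invisible(manifest)
}

# Translate drawn scar percentages into planted voxel counts (exact voxel
# counts of the annulus and of the plantable sector, so the measured
# percentage reproduces the drawn one up to rounding). The planted total
# is capped at the plantable sector capacity; the core / peri split
# follows the drawn peri percentage of total.
lge_from_truth <- function(pcfg, tr) {
  cnt <- annulus_voxel_counts(pcfg$grid_shape[1L], pcfg$grid_shape[2L])
  n_total <- min(round(tr$pct_mde_total / 100 * cnt$total), cnt$plantable)
  n_peri <- round(tr$pct_mde_peri / 100 * n_total)
  n_core <- n_total - n_peri
  generate_lge_phantom(pcfg, n_core = n_core, n_peri = n_peri,
                       n_slices = 3L)
}

# Voxel counts of the phantom myocardial annulus and of the sector
# available for infarct planting, matching generate_lge_phantom's geometry.
annulus_voxel_counts <- function(nr, nc) {
  geom <- phantom_annulus_geometry(nr, nc)
  rr <- matrix(rep(seq_len(nr), nc), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rad <- sqrt((rr - geom$center[1L])^2 + (cc - geom$center[2L])^2)
  annulus <- rad >= geom$r_endo & rad <= geom$r_epi
  ang <- voxel_angles(rr, cc, geom$center, 90)
  list(total = sum(annulus),
       plantable = sum(annulus & ang >= 10 & ang < 170))
}

#' Run the full quantification pipeline
#'
#' Executes simulate -> perfusion -> function -> LGE -> cohort statistics,
#' writing `perfusion.csv`, `function.csv`, `lge.csv`, the assembled
#' `cohort_measured.csv`, `cohort_comparisons.csv`, a text `report.txt`
#' and a `provenance.json` (canonical config hash, seed, package version).
#' Any stage failure leaves a `FAILED` marker naming the stage and
#' re-raises the error; partial outputs are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the measured cohort table, the cohort
#'   summary and the output paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    cmr_invalid("config must be a pipeline_config")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out, "FAILED"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste("stage:", name, "-", conditionMessage(e)),
                 file.path(out, "FAILED"))
      cmr_error(paste0("pipeline stage '", name, "' failed: ",
                       conditionMessage(e)),
                if (inherits(e, "cmr_invalid_config"))
                  "cmr_invalid_config" else "cmr_compute_error")
    })
  }

  manifest <- stage("simulate", simulate_cohort_studies(config))

  perf <- stage("perfusion", {
    rows <- lapply(seq_len(nrow(manifest)), function(i) {
      r <- quantify_perfusion(
        read_perfusion_study(file.path(out, manifest$perf_rest[i])),
        read_perfusion_study(file.path(out, manifest$perf_stress[i])))
      reg <- r$regions
      data.frame(subject_id = manifest$subject_id[i],
                 timepoint = manifest$timepoint[i],
                 mbf_rest_targeted = reg$mbf_rest[reg$label == "targeted"],
                 mbf_stress_targeted = reg$mbf_stress[reg$label == "targeted"],
                 mbf_rest_nontargeted = reg$mbf_rest[reg$label == "nontargeted"],
                 mbf_stress_nontargeted = reg$mbf_stress[reg$label == "nontargeted"],
                 mpr_targeted = reg$mpr[reg$label == "targeted"],
                 mpr_nontargeted = reg$mpr[reg$label == "nontargeted"])
    })
    do.call(rbind, rows)
  })
  write.csv(format_numeric(perf), file.path(out, "perfusion.csv"),
            row.names = FALSE)

  fun <- stage("function", {
    rows <- lapply(seq_len(nrow(manifest)), function(i) {
      vf <- quantify_function(
        read_contour_set(file.path(out, manifest$contours[i])))
      data.frame(subject_id = manifest$subject_id[i],
                 timepoint = manifest$timepoint[i],
                 edv_ml = vf$edv_ml, esv_ml = vf$esv_ml,
                 ef_pct = vf$ef_pct,
                 mass_g_per_m2 = vf$mass_g / config$bsa_m2,
                 thickening_pct_targeted = mean(vf$thickening_pct,
                                                na.rm = TRUE))
    })
    do.call(rbind, rows)
  })
  write.csv(format_numeric(fun), file.path(out, "function.csv"),
            row.names = FALSE)

  lge <- stage("lge", {
    rows <- lapply(seq_len(nrow(manifest)), function(i) {
      st <- read_lge_study(file.path(out, manifest$lge[i]))
      part <- partition_infarct(st, config$sd_total, config$sd_core)
      data.frame(subject_id = manifest$subject_id[i],
                 timepoint = manifest$timepoint[i],
                 mde_total_g = part$mde_total_g,
                 mde_core_g = part$mde_core_g,
                 mde_peri_g = part$mde_peri_g,
                 pct_mde_total = pct_infarct_of_lv(part),
                 pct_mde_core = part$pct_core_of_total,
                 pct_mde_peri = part$pct_peri_of_total)
    })
    do.call(rbind, rows)
  })
  write.csv(format_numeric(lge), file.path(out, "lge.csv"),
            row.names = FALSE)

  summary <- stage("cohort", {
    measured <- merge(merge(perf, fun, by = c("subject_id", "timepoint")),
                      lge, by = c("subject_id", "timepoint"))
    measured <- measured[order(measured$subject_id, measured$timepoint), ]
    write_cohort_csv(format_numeric(measured),
                     file.path(out, "cohort_measured.csv"))
    s <- summarize_cohort(measured, alpha = config$alpha)
    write.csv(format_numeric(s$comparisons),
              file.path(out, "cohort_comparisons.csv"), row.names = FALSE)
    writeLines(format_cohort_report(s), file.path(out, "report.txt"))
    s
  })

  # Provenance records the analysis parameters; the output location is not
  # part of the scientific configuration, so runs into different
  # directories remain byte-identical.
  cfg_rec <- unclass(config)
  cfg_rec$out_dir <- NULL
  jsonlite::write_json(list(
    config = jsonlite::fromJSON(canonical_config_json(cfg_rec)),
    config_hash = config_hash(cfg_rec),
    seed = config$seed,
    package = "cmrquant",
    version = as.character(packageVersion("cmrquant"))),
    file.path(out, "provenance.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(summary = summary, out_dir = out, manifest = manifest))
}

# Fixed 6-significant-digit formatting keeps CSV output platform-stable.
format_numeric <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- signif(df[[j]], 6)
  }
  df
}
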