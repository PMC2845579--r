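# Perfusion quantification: curve extraction, Fermi deconvolution, MPR and
# regional aggregation.

test_that("extract_curves reproduces per-sector means and baseline logic", {
  cfg <- small_cfg()
  model <- segment_model()
  mbf <- seq(0.4, 1.9, length.out = 16)
  st <- generate_perfusion_study(cfg, mbf, "rest", model)
  cur <- extract_curves(st)
  expect_equal(nrow(cur$tissue), cfg$n_frames)
  expect_equal(ncol(cur$tissue), 16L)

  # brute-force per-frame sector means (naive loop oracle)
  s <- 2L
  sec <- cmrquant:::assign_sectors(st$myo_mask[, , s], model, s)
  for (id in model$segment_id[model$slice_index == s][1:2]) {
    vox <- which(!is.na(sec) & sec == id, arr.ind = TRUE)
    naive <- vapply(seq_len(cfg$n_frames), function(f) {
      mean(st$image[, , s, f][vox])
    }, numeric(1))
    naive <- naive - mean(naive[1:cfg$n_baseline_frames])
    expect_equal(unname(cur$tissue[, as.character(id)]), naive,
                 tolerance = 1e-12)
  }

  # uniform image: every curve identically zero after baseline subtraction
  st_u <- st
  st_u$image <- array(100, dim(st$image))
  cur_u <- extract_curves(st_u)
  expect_true(all(abs(cur_u$aif) < 1e-12))
  expect_true(all(abs(cur_u$tissue) < 1e-12))

  # single-voxel blood pool: AIF equals that voxel's series minus baseline
  st_1 <- st
  st_1$blood_mask[] <- FALSE
  st_1$blood_mask[24, 24, 1] <- TRUE
  series <- st_1$image[24, 24, 1, ]
  expect_equal(extract_curves(st_1)$aif,
               series - mean(series[1:cfg$n_baseline_frames]))

  # empty sector: warned and excluded, not silently zero. Remove a wedge
  # wider than segment 1's sector so the sector stays empty even after
  # the mask centroid shifts.
  st_e <- st
  m1 <- st_e$myo_mask[, , 1]
  vox <- which(m1, arr.ind = TRUE)
  ctr <- colMeans(vox)
  ang <- cmrquant:::voxel_angles(vox[, 1], vox[, 2], ctr, 90)
  m1[vox[ang >= 350 | ang < 70, , drop = FALSE]] <- FALSE
  st_e$myo_mask[, , 1] <- m1
  expect_warning(cur_e <- extract_curves(st_e), "segment 1")
  expect_true(1L %in% cur_e$excluded)
  expect_false("1" %in% colnames(cur_e$tissue))

  # empty blood pool is an error
  st_b <- st
  st_b$blood_mask[] <- FALSE
  expect_error(extract_curves(st_b), class = "cmr_invalid_config")
})

test_that("frame-time jitter triggers uniform resampling", {
  cfg <- small_cfg()
  st <- generate_perfusion_study(cfg, rep(1, 16), "rest")
  jitter <- rep(c(-0.05, 0.05), length.out = cfg$n_frames - 2L)
  st$frame_times <- st$frame_times + c(0, jitter, 0)
  cur <- extract_curves(st)
  expect_equal(diff(cur$time), rep(cur$dt, cfg$n_frames - 1L))
})

test_that("Fermi deconvolution closes over the clinical flow range", {
  aif <- .fixture_aif
  cfg <- .fixture_cfg
  for (m in c(0.3, 0.67, 1.12, 2.01, 4.0)) {
    tis <- generate_tissue_curve(aif, m, cfg$fermi_shape)
    fit <- fermi_deconvolve(aif$signal, tis, dt = 1)
    expect_lt(abs(fit$mbf - m) / m, 0.01)
    expect_true(fit$converged)
  }

  # zero tissue curve -> zero flow
  fit0 <- fermi_deconvolve(aif$signal, numeric(length(aif$signal)), dt = 1)
  expect_equal(fit0$mbf, 0)

  # degenerate all-zero AIF is an error
  expect_error(fermi_deconvolve(numeric(40), rnorm(40), dt = 1),
               class = "cmr_compute_error")
})

test_that("fitted flow is scale-equivariant", {
  aif <- .fixture_aif
  tis <- generate_tissue_curve(aif, 1.5, .fixture_cfg$fermi_shape)
  base <- fermi_deconvolve(aif$signal, tis, dt = 1)$mbf
  doubled <- fermi_deconvolve(aif$signal, 2 * tis, dt = 1)$mbf
  both <- fermi_deconvolve(3 * aif$signal, 3 * tis, dt = 1)$mbf
  expect_equal(doubled, 2 * base, tolerance = 1e-4)
  expect_equal(both, base, tolerance = 1e-4)
})

test_that("first-pass windowing is insensitive at zero noise", {
  aif <- .fixture_aif
  tis <- generate_tissue_curve(aif, 1.2, .fixture_cfg$fermi_shape)
  win <- first_pass_window(aif$signal)
  ref <- fermi_deconvolve(aif$signal, tis, dt = 1, window = win)$mbf
  for (shift in c(-2L, 2L)) {
    w2 <- list(start = win$start, end = win$end + shift)
    m2 <- fermi_deconvolve(aif$signal, tis, dt = 1, window = w2)$mbf
    expect_lt(abs(m2 - ref) / ref, 0.005)
  }
})

test_that("MPR is the stress to rest flow ratio", {
  expect_equal(round(compute_mpr(0.67, 0.83), 1), 1.2)
  expect_equal(round(compute_mpr(0.97, 2.01), 1), 2.1)
  expect_equal(compute_mpr(1, 1), 1)
  expect_error(compute_mpr(0, 1.5), class = "cmr_compute_error")
  expect_error(compute_mpr(-0.2, 1.5), class = "cmr_compute_error")
})

test_that("regional aggregation is the unweighted segment mean", {
  model <- segment_model(targeted_segments = c(1L, 2L))
  v <- setNames(rep(0.8, 16), 1:16)
  agg <- aggregate_regions(v, model)
  expect_equal(agg$mean, c(0.8, 0.8))
  expect_equal(sum(agg$n_segments), 16L)

  v2 <- v
  v2[c("1", "2")] <- c(1.0, 1.4)
  agg2 <- aggregate_regions(v2, model)
  expect_equal(agg2$mean[agg2$label == "targeted"], 1.2)

  # a label class without segments is an error
  expect_error(aggregate_regions(v[3:16], model),
               class = "cmr_compute_error")
})

test_that("identical rest and stress studies give MPR exactly 1", {
  cfg <- small_cfg()
  st <- generate_perfusion_study(cfg, rep(c(0.7, 1.1), 8), "rest")
  st2 <- st
  st2$state <- "stress"
  res <- quantify_perfusion(st, st2)
  expect_true(all(res$segments$mpr == 1))
  expect_equal(res$regions$mpr, c(1, 1))
})

test_that("a planted regional flow difference is recovered", {
  cfg <- small_cfg()
  model <- segment_model()
  mbf_r <- ifelse(model$label == "targeted", 0.67, 0.97)
  mbf_s <- ifelse(model$label == "targeted", 0.83, 2.01)
  res <- quantify_perfusion(
    generate_perfusion_study(cfg, mbf_r, "rest", model),
    generate_perfusion_study(cfg, mbf_s, "stress", model))
  reg <- res$regions
  expect_equal(reg$mbf_rest[reg$label == "targeted"], 0.67,
               tolerance = 0.01)
  expect_equal(reg$mbf_stress[reg$label == "nontargeted"], 2.01,
               tolerance = 0.01)
  expect_equal(reg$mpr[reg$label == "targeted"], 0.83 / 0.67,
               tolerance = 0.01)
})
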