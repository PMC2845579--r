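# LGE scar quantification: remote reference statistics, SD-threshold
# partitioning, mass percentages and transmural extent.

make_lge <- function(img, remote_vox, myo = NULL) {
  myo <- myo %||% matrix(TRUE, nrow(img), ncol(img))
  remote <- matrix(FALSE, nrow(img), ncol(img))
  remote[remote_vox] <- TRUE
  lge_study(img, myo, remote, voxel_volume_ml = 0.1)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("remote statistics are the slice sample mean and SD", {
  img <- matrix(50, 10, 10)
  st <- suppressWarnings(make_lge(img, 1:4))
  expect_equal(suppressWarnings(remote_stats(st, 1)),
               c(mu = 50, sigma = 0))

  img2 <- matrix(0, 10, 10)
  img2[1:2] <- c(40, 60)
  st2 <- make_lge(img2, 1:2)
  expect_warning(rs <- remote_stats(st2, 1), "unreliable")
  expect_equal(rs, c(mu = 50, sigma = sd(c(40, 60))))

  # random remote region matches direct recomputation
  set.seed(2)
  img3 <- matrix(rnorm(400, 100, 12), 20, 20)
  st3 <- make_lge(img3, 5:40)
  expect_equal(remote_stats(st3, 1),
               c(mu = mean(img3[5:40]), sigma = sd(img3[5:40])))

  # empty remote ROI is an error
  st4 <- st3
  st4$remote_mask[] <- FALSE
  expect_error(remote_stats(st4, 1), class = "cmr_compute_error")
})

test_that("threshold arithmetic classifies voxels as specified", {
  # remote mu = 100, sigma = 10: thresholds 120 (total) and 130 (core)
  img <- matrix(100, 12, 12)
  set.seed(3)
  rem <- 1:24
  img[rem] <- 100 + 10 * cmrquant:::bounded_z(rnorm(24))
  img[30] <- 115  # below total threshold: excluded
  img[31] <- 125  # peri band
  img[32] <- 135  # core
  img[33] <- 130  # exactly at the core threshold: stays peri
  st <- make_lge(img, rem)
  p <- partition_infarct(st)
  expect_false(p$total[30])
  expect_true(p$peri[31] && !p$core[31])
  expect_true(p$core[32])
  expect_true(p$peri[33] && !p$core[33])
  expect_equal(sum(p$total), 3)

  # nothing above mu + 2 sigma: empty partition, 0% of LV
  img0 <- matrix(100, 12, 12)
  img0[rem] <- img[rem]
  st0 <- make_lge(img0, rem)
  p0 <- partition_infarct(st0)
  expect_equal(sum(p0$total), 0)
  expect_equal(pct_infarct_of_lv(p0), 0)
  expect_true(is.na(p0$pct_core_of_total))

  # invalid threshold ordering rejected before compute
  expect_error(partition_infarct(st, sd_total = 3, sd_core = 2),
               class = "cmr_invalid_config")
})

test_that("partition matches the exhaustive per-voxel oracle", {
  set.seed(7)
  for (i in 1:50) {
    img <- matrix(rnorm(32 * 32, 100, 25), 32, 32)
    myo <- matrix(runif(32 * 32) < 0.8, 32, 32)
    rem_idx <- sample(which(myo), 20)
    remote <- matrix(FALSE, 32, 32)
    remote[rem_idx] <- TRUE
    st <- lge_study(img, myo, remote, voxel_volume_ml = 0.05)
    p <- partition_infarct(st)
    o <- partition_oracle(img, myo, remote)
    expect_identical(p$total[, , 1], o$total)
    expect_identical(p$core[, , 1], o$core)
    expect_identical(p$peri[, , 1], o$peri)
    # conservation: core + peri = total, disjointly
    expect_identical(p$total, p$core | p$peri)
    expect_false(any(p$core & p$peri))
  }
})

test_that("partition is intensity-shift invariant and threshold-monotone", {
  set.seed(9)
  img <- matrix(rnorm(32 * 32, 100, 25), 32, 32)
  myo <- matrix(TRUE, 32, 32)
  remote <- matrix(FALSE, 32, 32)
  remote[sample.int(1024, 30)] <- TRUE
  st <- lge_study(img, myo, remote, voxel_volume_ml = 0.05)
  p <- partition_infarct(st)

  st_shift <- lge_study(img + 37.5, myo, remote, voxel_volume_ml = 0.05)
  p_shift <- partition_infarct(st_shift)
  expect_identical(p$total, p_shift$total)
  expect_identical(p$core, p_shift$core)

  # raising the total threshold 2 -> 3 SD never increases the total mass,
  # and reproduces the core mass of the (2, 3) partition
  p3 <- partition_infarct(st, sd_total = 3, sd_core = 4)
  expect_lte(p3$mde_total_g, p$mde_total_g)
  expect_equal(p3$mde_total_g, p$mde_core_g)
})

test_that("scar mass percentages follow their definitions", {
  cfg <- small_cfg()
  set.seed(21)
  ph <- generate_lge_phantom(cfg, n_core = 40L, n_peri = 60L)
  p <- partition_infarct(ph)
  hand_total_g <- 100 * ph$voxel_volume_ml * 1.05
  expect_equal(p$mde_total_g, hand_total_g)
  expect_equal(pct_infarct_of_lv(p, lv_mass_g = 10 * hand_total_g), 10)
  expect_equal(pct_infarct_of_lv(p),
               100 * hand_total_g / (sum(ph$myo_mask) *
                                       ph$voxel_volume_ml * 1.05))
  expect_equal(p$pct_core_of_total + p$pct_peri_of_total, 100)
  expect_error(pct_infarct_of_lv(p, lv_mass_g = 0),
               class = "cmr_invalid_config")
})

test_that("transmural extent classifies wall involvement", {
  cfg <- small_cfg()
  set.seed(31)
  # the planted sector fills the full wall thickness -> class > 75%
  ph <- generate_lge_phantom(cfg, n_core = 150L, n_peri = 0L)
  p <- partition_infarct(ph)
  tm <- transmural_extent(p, ph$contours$endo, ph$contours$epi)
  expect_equal(tm$study_class, ">75%")
  expect_true(any(tm$sectors$transmurality_pct > 75, na.rm = TRUE))

  # no enhancement anywhere -> every sector < 50% (0%)
  ph0 <- generate_lge_phantom(cfg, n_core = 0L, n_peri = 0L)
  tm0 <- transmural_extent(partition_infarct(ph0),
                           ph0$contours$endo, ph0$contours$epi)
  expect_equal(tm0$study_class, "<50%")
  expect_true(all(tm0$sectors$transmurality_pct == 0, na.rm = TRUE))

  # boundary rule: exactly 50% falls in the middle class
  expect_equal(cmrquant:::classify_transmurality(c(49.9, 50, 74.9, 75, 80)),
               c("<50%", "50-75%", "50-75%", ">75%", ">75%"))
})

test_that("half-wall enhancement lands in the 50-75% class", {
  # build a slice whose infarct occupies the inner 60% of the wall in one
  # sector (margin above the 50% boundary covers voxel rounding); the
  # measured transmural fraction must classify as 50-75%
  nr <- 64L
  geom <- cmrquant:::phantom_annulus_geometry(nr, nr)
  rr <- matrix(rep(1:nr, nr), nr, nr)
  cc <- matrix(rep(1:nr, each = nr), nr, nr)
  rad <- sqrt((rr - geom$center[1])^2 + (cc - geom$center[2])^2)
  annulus <- rad >= geom$r_endo & rad <= geom$r_epi
  ang <- atan2(cc - geom$center[2], rr - geom$center[1]) * 180 / pi
  img <- matrix(100, nr, nr)
  remote <- annulus & ang > -170 & ang < -100
  set.seed(41)
  img[remote] <- 100 + 10 * cmrquant:::bounded_z(rnorm(sum(remote)))
  r_half <- geom$r_endo + 0.6 * (geom$r_epi - geom$r_endo)
  infarct <- annulus & rad <= r_half & ang > 10 & ang < 80
  img[infarct] <- 200
  st <- lge_study(img, annulus, remote, voxel_volume_ml = 0.05)
  p <- partition_infarct(st)
  tm <- transmural_extent(p,
                          circle_polygon(rev(geom$center), geom$r_endo),
                          circle_polygon(rev(geom$center), geom$r_epi),
                          n_sectors = 36L)
  expect_equal(tm$study_class, "50-75%")
})
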