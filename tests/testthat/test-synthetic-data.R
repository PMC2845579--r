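# Phantom generators: AIF shape, tissue-curve forward model, planted LGE
# partitions and the paired virtual cohort.

test_that("config validation rejects impossible acquisitions", {
  expect_error(phantom_config(n_frames = 20L), class = "cmr_invalid_config")
  expect_error(phantom_config(frame_interval_s = 0),
               class = "cmr_invalid_config")
  expect_error(phantom_config(noise_sd = -1), class = "cmr_invalid_config")
  es <- default_effect_sizes()
  es$ef_pct$baseline[2] <- -5
  expect_error(phantom_config(effect_sizes = es),
               class = "cmr_invalid_config")
})

test_that("AIF is a gamma-variate bolus with the analytic peak time", {
  cfg <- .fixture_cfg
  ap <- cfg$aif_params

  # no recirculation: pure gamma-variate, zero before onset
  ap0 <- modifyList(ap, list(recirc_fraction = 0))
  cfg0 <- small_cfg(aif_params = ap0)
  aif0 <- generate_aif(cfg0)
  expect_equal(aif0$signal,
               gamma_variate(aif0$time, ap$amplitude, ap$onset_s,
                             ap$shape, ap$scale_s))
  expect_true(all(aif0$signal[aif0$time <= ap$onset_s] == 0))

  # zero amplitude: identically zero curve
  cfgA <- small_cfg(aif_params = modifyList(ap, list(amplitude = 0)))
  expect_true(all(generate_aif(cfgA)$signal == 0))

  # peak at onset + shape * scale, against a 1000x oversampled grid
  t_dense <- seq(0, max(aif0$time), length.out = 1000L * cfg$n_frames)
  dense <- gamma_variate(t_dense, ap$amplitude, ap$onset_s, ap$shape,
                         ap$scale_s)
  t_peak_oracle <- t_dense[which.max(dense)]
  expect_equal(t_peak_oracle, ap$onset_s + ap$shape * ap$scale_s,
               tolerance = 1e-3)
  # sampled curve peaks at the frame nearest the analytic mode
  expect_equal(aif0$time[which.max(aif0$signal)],
               ap$onset_s + ap$shape * ap$scale_s,
               tolerance = cfg$frame_interval_s)

  # single dominant first-pass peak before the recirculation bump
  aif <- generate_aif(cfg)
  pk <- which.max(aif$signal)
  expect_lt(aif$time[pk], ap$onset_s + ap$recirc_delay_s)
  expect_true(all(aif$signal >= 0))
})

test_that("tissue forward model matches brute-force convolution", {
  aif <- .fixture_aif
  dt <- 1

  # zero flow: identically zero curve
  expect_true(all(generate_tissue_curve(aif, 0) == 0))
  expect_error(generate_tissue_curve(aif, -1), class = "cmr_invalid_config")

  # unit-amplitude step response: tissue = running integral of the AIF
  n <- length(aif$signal)
  h_step <- rep(1, n)
  expect_equal(convolve_ir(aif$signal, h_step, dt),
               cumsum(aif$signal) * dt)
  expect_equal(convolve_ir(aif$signal, h_step, dt),
               conv_oracle(aif$signal, h_step, dt))

  # Fermi response against the double-loop oracle
  h <- fermi_ir((seq_len(n) - 1) * dt, 1.3, 2, 8, 1)
  expect_equal(convolve_ir(aif$signal, h, dt),
               conv_oracle(aif$signal, h, dt), tolerance = 1e-12)

  # noise-free curves are non-negative
  expect_true(all(generate_tissue_curve(aif, 2.5) >= 0))
})

test_that("noise-free tissue curves close the deconvolution loop", {
  fit <- fermi_deconvolve(.fixture_aif$signal,
                          generate_tissue_curve(.fixture_aif, 0.67),
                          dt = 1)
  expect_lt(abs(fit$mbf - 0.67) / 0.67, 0.01)
  expect_true(fit$converged)
})

test_that("planted LGE partitions are exactly recoverable", {
  cfg <- .fixture_cfg
  set.seed(11)

  # nothing planted -> empty partition
  ph0 <- generate_lge_phantom(cfg, n_core = 0L, n_peri = 0L)
  p0 <- partition_infarct(ph0)
  expect_equal(sum(p0$total), 0)
  expect_equal(p0$mde_total_g, 0)

  # 40 core + 60 peri at the default margins -> recovered exactly
  ph <- generate_lge_phantom(cfg, n_core = 40L, n_peri = 60L)
  p <- partition_infarct(ph)
  expect_equal(sum(p$core), 40)
  expect_equal(sum(p$peri), 60)
  expect_identical(p$core, ph$truth$core)
  expect_identical(p$peri, ph$truth$peri)
  expect_equal(p$pct_core_of_total, 40)
  expect_equal(p$pct_peri_of_total, 60)

  # degenerate remote SD: everything above the remote mean is core
  phd <- generate_lge_phantom(cfg, n_core = 40L, n_peri = 60L,
                              remote_sd = 0)
  pd <- partition_infarct(phd)
  expect_equal(sum(pd$core), 100)
  expect_equal(sum(pd$peri), 0)

  # planted region must fit in the plantable sector
  expect_error(generate_lge_phantom(cfg, n_core = 10000L, n_peri = 0L),
               class = "cmr_invalid_config")
})

test_that("virtual cohorts reproduce the configured effect sizes", {
  # Monte-Carlo over 200 seeds: grand mean of the targeted-MPR draws
  # within 3 SE of the configured means
  means_b <- means_f <- numeric(200)
  for (s in 1:200) {
    tab <- generate_cohort(phantom_config(seed = s, n_subjects = 12L))
    means_b[s] <- mean(tab$mpr_targeted[tab$timepoint == "baseline"])
    means_f[s] <- mean(tab$mpr_targeted[tab$timepoint == "followup"])
  }
  se_b <- 0.3 / sqrt(200 * 12)
  se_f <- 0.4 / sqrt(200 * 12)
  expect_lt(abs(mean(means_b) - 1.2), 3 * se_b)
  expect_lt(abs(mean(means_f) - 1.5), 3 * se_f)

  # zero SDs: every subject sits exactly at the configured means
  es0 <- default_effect_sizes()
  for (m in names(es0)) {
    es0[[m]]$baseline[2] <- 0
    es0[[m]]$followup[2] <- 0
  }
  tab0 <- generate_cohort(phantom_config(seed = 5, n_subjects = 4L,
                                         effect_sizes = es0))
  expect_true(all(tab0$ef_pct[tab0$timepoint == "baseline"] == 51))
  expect_true(all(tab0$mpr_targeted[tab0$timepoint == "followup"] == 1.5))

  # determinism: same config -> byte-identical cohort
  c1 <- generate_cohort(phantom_config(seed = 42, n_subjects = 6L))
  c2 <- generate_cohort(phantom_config(seed = 42, n_subjects = 6L))
  expect_identical(c1, c2)

  expect_error(generate_cohort(phantom_config(n_subjects = 1L)),
               class = "cmr_invalid_config")
})

test_that("phantom perfusion studies are deterministic under a fixed seed", {
  cfg <- small_cfg(noise_sd = 1)
  mbf <- rep(c(0.7, 1.0), 8)
  set.seed(123)
  s1 <- generate_perfusion_study(cfg, mbf, "rest")
  set.seed(123)
  s2 <- generate_perfusion_study(cfg, mbf, "rest")
  expect_identical(s1, s2)
})
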