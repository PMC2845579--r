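# Shared fixtures: a compact phantom configuration and a cached noise-free
# AIF, reused across test files to keep the suite fast.

small_cfg <- function(...) {
  phantom_config(grid_shape = c(48L, 48L), n_frames = 40L, ...)
}

.fixture_cfg <- small_cfg()
.fixture_aif <- generate_aif(.fixture_cfg)

# Independent brute-force discrete convolution (double loop), used as the
# oracle for the vectorised forward model.
conv_oracle <- function(x, h, dt) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(i)) acc <- acc + x[j] * h[i - j + 1L]
    out[i] <- acc * dt
  }
  out
}

# Independent textbook paired t: mean difference over its standard error,
# two-sided p from the t distribution.
paired_t_oracle <- function(b, f) {
  d <- f - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# Exhaustive per-voxel threshold classification oracle for one LGE slice.
partition_oracle <- function(img, myo, remote, sd_total = 2, sd_core = 3) {
  v <- img[remote]
  mu <- mean(v)
  sg <- if (length(v) > 1L) sd(v) else 0
  total <- core <- matrix(FALSE, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      if (!myo[r, c]) next
      if (img[r, c] > mu + sd_total * sg) total[r, c] <- TRUE
      if (img[r, c] > mu + sd_core * sg) core[r, c] <- TRUE
    }
  }
  list(total = total, core = core, peri = total & !core)
}
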