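n_t_for <- function(sfreq) length(seq(-0.05, 0.3 - 1 / sfreq, by = 1 / sfreq))

# an epoch holding a Gaussian-enveloped 10 Hz burst peaking at `peak_uv` on
# one channel, zero pre-stimulus, already spatially balanced so average
# referencing and baseline correction leave it (nearly) unchanged
burst_epoch <- function(peak_uv, mont, sfreq = 512, with_keeper = FALSE) {
  t <- seq(-0.05, 0.3 - 1 / sfreq, by = 1 / sfreq)
  n_ch <- nrow(mont)
  env <- exp(-0.5 * ((t - 0.15) / 0.04)^2)
  wave <- peak_uv * env * sin(2 * pi * 10 * (t - 0.15) + pi / 2)
  n_ep <- if (with_keeper) 2L else 1L
  a <- array(0, c(n_ep, n_ch, length(t)))
  a[1, 1, ] <- wave
  for (ch in 2:n_ch) a[1, ch, ] <- -wave / (n_ch - 1)
  if (with_keeper) a[2, 1, ] <- wave / peak_uv     # quiet 1 uV companion
  epoched_eeg(a, sfreq, -0.05, montage = mont)
}

test_that("the +/-20 uV rejection rule drops a 25 uV epoch and keeps 15 uV", {
  mont <- montage_sphere(16)
  # each input holds the burst epoch plus a quiet companion, since a cell
  # losing every epoch is a hard error by contract
  hot <- preprocess_epochs(burst_epoch(25 * 16 / 15, mont, with_keeper = TRUE))
  cold <- preprocess_epochs(burst_epoch(15 * 16 / 15, mont,
                                        with_keeper = TRUE))
  # (the 16/15 factor anticipates the average reference of the balanced
  # pattern, so the processed amplitudes are ~25 and ~15)
  expect_gt(hot$report$max_abs_uv[1], 20)
  expect_lt(cold$report$max_abs_uv[1], 20)
  expect_equal(hot$report$kept, c(FALSE, TRUE))
  expect_equal(cold$report$kept, c(TRUE, TRUE))
  expect_error(preprocess_epochs(burst_epoch(30, mont)), "all epochs rejected")
})

test_that("constant-zero epochs pass through every stage unchanged", {
  mont <- montage_sphere(8)
  z <- epoched_eeg(array(0, c(3, 8, n_t_for(512))), 512, montage = mont)
  out <- preprocess_epochs(z)
  expect_true(all(out$report$kept))
  expect_equal(max(abs(out$clean$data)), 0)
})

test_that("band-pass attenuation matches the designed transfer function", {
  mont <- montage_sphere(8)
  sf <- 512
  t <- seq(-0.05, 0.3 - 1 / sf, by = 1 / sf)
  sine_epoch <- function(f) {
    a <- array(0, c(1, 8, length(t)))
    for (ch in 1:8) a[1, ch, ] <- sin(2 * pi * f * t) * (ch %% 2 * 2 - 1)
    epoched_eeg(a, sf, -0.05, montage = mont)
  }
  amp_at <- function(f) {
    p <- preprocess_epochs(sine_epoch(f),
                           preproc_config(reject_threshold_uv = 1e9))
    y <- p$clean$data[1, 1, 60:150]; tt <- t[60:150]
    co <- coef(lm(y ~ sin(2 * pi * f * tt) + cos(2 * pi * f * tt)))
    unname(sqrt(co[2]^2 + co[3]^2))
  }
  measured_db <- 20 * log10(amp_at(10) / amp_at(50))
  # oracle: squared magnitude (forward-backward) of the designed filter
  bf <- signal::butter(4, c(1, 40) / (sf / 2), type = "pass")
  H2 <- function(f) {
    z <- exp(-1i * 2 * pi * f / sf)
    abs(sum(bf$b * z^(0:(length(bf$b) - 1))) /
          sum(bf$a * z^(0:(length(bf$a) - 1))))^2
  }
  designed_db <- 20 * log10(H2(10) / H2(50))
  expect_equal(measured_db, designed_db, tolerance = 0.15)  # ~18 dB
  expect_gt(measured_db, 15)
})

test_that("the vectorized zero-phase filter matches filtfilt at steady state", {
  set.seed(3)
  sf <- 512
  x <- as.numeric(stats::filter(rnorm(4096), rep(1, 5) / 5, sides = 1))
  x[is.na(x)] <- 0
  # an 8 Hz low edge keeps the slowest pole's transient short, so the two
  # paddings agree to near machine precision away from the edges
  bf <- signal::butter(4, c(8, 40) / (sf / 2), type = "pass")
  mine <- evtopo:::iir_filtfilt_rows(bf$b, bf$a, rbind(x, 2 * x))[1, ]
  ref <- as.numeric(signal::filtfilt(bf, x))
  mid <- 1500:2500                     # away from both edges
  expect_lt(max(abs(mine[mid] - ref[mid])), 1e-6 * max(abs(ref)))
})

test_that("referencing and baseline correction hit their exact targets", {
  set.seed(8)
  mont <- montage_sphere(12)
  a <- array(rnorm(5 * 12 * n_t_for(512), sd = 3), c(5, 12, n_t_for(512)))
  out <- preprocess_epochs(epoched_eeg(a, 512, montage = mont),
                           preproc_config(reject_threshold_uv = 1e9))
  d <- out$clean$data
  scale <- max(abs(d))
  for (e in 1:5) {
    expect_lt(max(abs(colMeans(d[e, , ]))), 1e-9 * scale)      # avg ref
    bl <- 1:26                                                 # pre-stimulus
    expect_lt(max(abs(rowMeans(d[e, , bl]))), 1e-9 * scale)    # baseline
  }
})

test_that("rejection is monotone in the threshold and deterministic", {
  set.seed(21)
  mont <- montage_sphere(8)
  a <- array(rnorm(20 * 8 * n_t_for(512), sd = 8), c(20, 8, n_t_for(512)))
  ep <- epoched_eeg(a, 512, montage = mont)
  kept <- vapply(c(5, 10, 20, 40), function(th) {
    tryCatch(
      sum(preprocess_epochs(ep,
                            preproc_config(reject_threshold_uv = th))$report$kept),
      error = function(e) 0)      # a cell losing every epoch is a hard error
  }, 0)
  expect_true(all(diff(kept) >= 0))
  r1 <- preprocess_epochs(ep); r2 <- preprocess_epochs(ep)
  expect_identical(r1$clean$data, r2$clean$data)
})

test_that("downsampling halves the rate and preserves a passband tone", {
  mont <- montage_sphere(4)
  sf <- 1024
  t <- seq(-0.05, 0.3 - 1 / sf, by = 1 / sf)
  a <- array(0, c(1, 4, length(t)))
  for (ch in 1:4) a[1, ch, ] <- 10 * sin(2 * pi * 12 * t) * (ch %% 2 * 2 - 1)
  out <- preprocess_epochs(epoched_eeg(a, sf, -0.05, montage = mont),
                           preproc_config(reject_threshold_uv = 1e9))
  expect_equal(out$clean$sfreq, 512)
  y <- out$clean$data[1, 1, 60:150]
  tt <- seq(-0.05, by = 1 / 512, length.out = dim(out$clean$data)[3])[60:150]
  co <- coef(lm(y ~ sin(2 * pi * 12 * tt) + cos(2 * pi * 12 * tt)))
  expect_equal(unname(sqrt(co[2]^2 + co[3]^2)), 10, tolerance = 0.05)
  expect_error(preprocess_epochs(epoched_eeg(a, 700, -0.05, montage = mont)),
               "integer")
})

test_that("spherical spline interpolation reproduces constants and smooth
           fields and leaves good channels untouched", {
  m64 <- montage_1010_64()
  cm <- matrix(7, 64, 2)
  out <- interpolate_bad_channels(cm, c(5, 40), m64)
  expect_lt(max(abs(out - 7)), 1e-6)
  # identity on empty bad set
  set.seed(2)
  x <- matrix(rnorm(64 * 3), 64)
  expect_identical(interpolate_bad_channels(x, integer(), m64), x)
  # leave-one-out on a noiseless dipolar field: median error <= 10% of GFP
  sp <- build_source_space(60, 20, 26)
  lf <- leadfield_single_sphere(sp, m64, 90)
  node <- which.max(sp$nodes[, 3])
  topo <- lf$L[, 3 * (node - 1) + 3, drop = FALSE]
  errs <- vapply(1:64, function(ch) {
    est <- interpolate_bad_channels(topo, ch, m64)
    # good channels untouched
    expect_identical(est[-ch, , drop = FALSE], topo[-ch, , drop = FALSE])
    abs(est[ch, 1] - topo[ch, 1])
  }, 0)
  expect_lt(median(errs), 0.1 * gfp(topo[, 1]))
  # labels are accepted, too many bad channels are not
  est <- interpolate_bad_channels(topo, "Cz", m64)
  expect_identical(est, interpolate_bad_channels(topo, match("Cz", m64$label),
                                                 m64))
  expect_error(interpolate_bad_channels(topo, 1:62, m64), "too many")
})

test_that("averaging reduces noise at the 1/sqrt(N) rate and validates cells", {
  set.seed(31)
  mont <- montage_sphere(8)
  n_ep <- 480; n_t <- 50; sdv <- 2
  mk <- function(cond) {
    a <- array(rnorm(n_ep * 8 * n_t, sd = sdv), c(n_ep, 8, n_t))
    epoched_eeg(a, 512, subject = "s01", condition = cond, montage = mont)
  }
  cells <- lapply(design_cells()$condition, mk)
  ev <- average_epochs(cells)
  ms <- ev$evoked$s01$congruent_synchronous
  # average reference removes 1/8 of the variance; expected RMS of the
  # referenced mean is sd * sqrt(1 - 1/8) / sqrt(N)
  expect_equal(sqrt(mean(ms^2)), sdv * sqrt(7 / 8) / sqrt(n_ep),
               tolerance = 0.2)
  expect_equal(ev$n_epochs_used$n_epochs, rep(n_ep, 4))
  # identical epochs average to any single epoch
  one <- array(rnorm(8 * n_t), c(1, 8, n_t))
  rep3 <- array(one[rep(1, 3), , ], c(3, 8, n_t))
  cells2 <- lapply(design_cells()$condition, function(cond)
    epoched_eeg(rep3, 512, subject = "s01", condition = cond, montage = mont))
  ev2 <- average_epochs(cells2)
  ref <- sweep(one[1, , ], 2, colMeans(one[1, , ]))
  expect_equal(ev2$evoked$s01$congruent_synchronous, ref, tolerance = 1e-12)
  # an empty cell is a hard error
  empty <- epoched_eeg(array(numeric(0), c(0, 8, n_t)), 512, subject = "s01",
                       condition = "congruent_synchronous", montage = mont)
  expect_error(average_epochs(list(empty)), "no epochs")
})

test_that("robust-variance bad channel detection flags a dead channel", {
  set.seed(4)
  mont <- montage_sphere(16)
  a <- array(rnorm(10 * 16 * 60), c(10, 16, 60))
  a[, 7, ] <- a[, 7, ] * 40           # one wild channel
  bad <- detect_bad_channels(epoched_eeg(a, 512, montage = mont))
  expect_identical(bad, 7L)
  expect_length(detect_bad_channels(
    epoched_eeg(array(rnorm(10 * 16 * 60), c(10, 16, 60)), 512,
                montage = mont)), 0)
})
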