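#' Preprocessing configuration
#'
#' Defaults mirror a standard somatosensory evoked potential chain: 512 Hz
#' target rate, 1-40 Hz zero-phase band-pass (4th order Butterworth applied
#' forward-backward), average reference, baseline correction over the
#' pre-stimulus interval, and rejection of any epoch whose post-reference,
#' post-baseline amplitude exceeds +/-20 uV on any channel at any sample.
#'
#' @param target_sfreq target sampling rate (samples/s).
#' @param bandpass `c(low, high)` Hz; low < high < Nyquist of the target rate.
#' @param epoch_window,baseline_window half-open windows `[start, end)` in s
#'   relative to stimulus onset; baseline must lie within the epoch.
#' @param reject_threshold_uv absolute amplitude criterion in uV.
#' @param bad_channel_z robust-variance |z| threshold for flagging bad
#'   channels.
#' @return list of class `preproc_config`.
#' @export
preproc_config <- function(target_sfreq = 512, bandpass = c(1, 40),
                           epoch_window = c(-0.05, 0.3),
                           baseline_window = c(-0.05, 0),
                           reject_threshold_uv = 20,
                           bad_channel_z = 3) {
  stopifnot(bandpass[1] > 0, bandpass[1] < bandpass[2],
            bandpass[2] < target_sfreq / 2,
            reject_threshold_uv > 0,
            baseline_window[1] >= epoch_window[1],
            baseline_window[2] <= epoch_window[2])
  structure(list(target_sfreq = target_sfreq, bandpass = bandpass,
                 epoch_window = epoch_window,
                 baseline_window = baseline_window,
                 reject_threshold_uv = reject_threshold_uv,
                 bad_channel_z = bad_channel_z),
            class = "preproc_config")
}

#' Preprocess stimulus-locked epochs
#'
#' Fixed order of operations: downsample (integer-factor decimation with
#' anti-alias filtering) -> zero-phase band-pass -> average reference ->
#' baseline correction (per channel, pre-stimulus mean) -> amplitude
#' rejection. After baseline correction every channel's pre-stimulus mean
#' is zero to numerical precision. The rejection criterion is the strictest
#' reading of an absolute threshold: an epoch is dropped when |amplitude|
#' exceeds the threshold on any channel at any sample of the processed
#' epoch.
#'
#' @param raw an [epoched_eeg()].
#' @param cfg a [preproc_config()].
#' @param ica_unmixing optional hook: a function applied to each epoch's
#'   channels x samples matrix after referencing (e.g., projecting out
#'   externally identified artifact components); the identity when NULL.
#' @return list with `clean` (an `epoched_eeg` of the kept epochs) and
#'   `report` (tibble: epoch, max_abs_uv, kept).
#' @export
preprocess_epochs <- function(raw, cfg = preproc_config(), ica_unmixing = NULL) {
  stopifnot(inherits(raw, "epoched_eeg"), inherits(cfg, "preproc_config"))
  if (raw$sfreq < cfg$target_sfreq) {
    abort("input rate is below the target rate; cannot downsample")
  }
  d <- dim(raw$data)
  factor <- raw$sfreq / cfg$target_sfreq
  if (abs(factor - round(factor)) > 1e-9) {
    abort("downsampling requires an integer rate ratio")
  }
  factor <- as.integer(round(factor))
  # signals as rows of one big matrix: (epochs * channels) x samples
  X <- matrix(aperm(raw$data, c(3, 1, 2)), nrow = d[3])  # samples x (ep*ch)
  X <- t(X)
  if (factor > 1L) {
    aa <- signal::butter(8, 0.8 / factor, type = "low")
    X <- iir_filtfilt_rows(aa$b, aa$a, X)
    X <- X[, seq(1, d[3], by = factor), drop = FALSE]
  }
  n_out <- ncol(X)
  bf <- signal::butter(4, cfg$bandpass / (cfg$target_sfreq / 2), type = "pass")
  X <- iir_filtfilt_rows(bf$b, bf$a, X)
  out <- aperm(array(t(X), c(n_out, d[1], d[2])), c(2, 3, 1))
  # average reference, sample-wise, per epoch
  for (e in seq_len(d[1])) {
    out[e, , ] <- average_reference(out[e, , , drop = TRUE])
    if (!is.null(ica_unmixing)) out[e, , ] <- ica_unmixing(out[e, , ])
  }
  # baseline: subtract each channel's pre-stimulus mean
  bl <- window_to_samples(cfg$baseline_window, raw$t0, cfg$target_sfreq, n_out)
  for (e in seq_len(d[1])) {
    m <- out[e, , , drop = TRUE]
    out[e, , ] <- m - rowMeans(m[, bl, drop = FALSE])
  }
  max_abs <- apply(abs(out), 1, max)
  kept <- max_abs <= cfg$reject_threshold_uv
  report <- tibble::tibble(
    subject = raw$subject, condition = raw$condition,
    epoch = seq_len(d[1]), max_abs_uv = max_abs, kept = kept)
  if (!any(kept)) {
    abort(sprintf("all epochs rejected for subject %s, condition %s",
                  raw$subject, raw$condition))
  }
  clean <- epoched_eeg(out[kept, , , drop = FALSE], cfg$target_sfreq, raw$t0,
                       raw$subject, raw$condition, raw$montage)
  list(clean = clean, report = report)
}

# Zero-phase IIR filtering of many signals at once (one per row), forward
# then backward, with odd-reflection edge padding. Equivalent to filtfilt
# applied row-wise but vectorized across signals: the time recursion runs
# over columns with whole-column vector operations.
iir_filtfilt_rows <- function(b, a, X) {
  b <- b / a[1]; a <- a / a[1]
  nf <- max(length(a), length(b))
  pad <- 3L * (nf - 1L)
  n <- ncol(X)
  if (n <= pad) abort("signal too short for the filter's edge padding")
  # odd reflection: 2*x[1] - x[pad+1 .. 2], and symmetric at the right edge
  left <- 2 * X[, 1] - X[, (pad + 1L):2L, drop = FALSE]
  right <- 2 * X[, n] - X[, (n - 1L):(n - pad), drop = FALSE]
  Y <- cbind(left, X, right)
  run <- function(Y) {
    nb <- length(b); na <- length(a)
    Z <- matrix(0, nrow(Y), ncol(Y))
    for (t in seq_len(ncol(Y))) {
      acc <- b[1] * Y[, t]
      if (t >= 2 && nb >= 2) {
        for (i in seq(2, min(nb, t))) acc <- acc + b[i] * Y[, t - i + 1L]
      }
      if (t >= 2 && na >= 2) {
        for (j in seq(2, min(na, t))) acc <- acc - a[j] * Z[, t - j + 1L]
      }
      Z[, t] <- acc
    }
    Z
  }
  Y <- run(Y)
  Y <- Y[, ncol(Y):1, drop = FALSE]
  Y <- run(Y)
  Y <- Y[, ncol(Y):1, drop = FALSE]
  Y[, (pad + 1L):(pad + n), drop = FALSE]
}

#' Flag bad channels by robust variance
#'
#' Channels whose log-variance (over all epochs and samples) deviates from
#' the montage median by more than `z` robust z-units (median/MAD) are
#' flagged for interpolation.
#'
#' @param epochs an [epoched_eeg()].
#' @param z robust z threshold (default 3).
#' @return integer vector of flagged channel indices (possibly empty).
#' @export
detect_bad_channels <- function(epochs, z = 3) {
  v <- apply(epochs$data, 2, function(x) var(as.vector(x)))
  lv <- log(v + .Machine$double.eps)
  med <- stats::median(lv)
  s <- stats::mad(lv)
  if (s == 0) return(integer())
  which(abs(lv - med) / s > z)
}

# Perrin-style spherical spline basis: g(x) = sum_n (2n+1) /
# (n^m (n+1)^m) P_n(x) / (4 pi), m = 4, truncated at n = 50.
spline_g <- function(x, m = 4, nmax = 50) {
  P <- legendre_terms(x, nmax)$P
  ns <- seq_len(nmax)
  w <- (2 * ns + 1) / (ns^m * (ns + 1)^m)
  as.numeric(P[, ns + 1L, drop = FALSE] %*% w) / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces flagged channels of a channels x samples matrix with spherical
#' spline estimates (order m = 4) computed from the remaining channels on
#' the unit sphere. Good channels are returned untouched; a constant
#' topography is reproduced exactly.
#'
#' @param m channels x samples matrix (uV).
#' @param bad integer indices (or labels) of channels to rebuild.
#' @param montage the [electrode_montage()] for the rows of `m`.
#' @return matrix of the same shape.
#' @export
interpolate_bad_channels <- function(m, bad, montage) {
  if (is.character(bad)) bad <- match(bad, montage$label)
  bad <- sort(unique(as.integer(bad)))
  if (!length(bad)) return(m)
  if (any(is.na(bad)) || any(bad < 1) || any(bad > nrow(m))) {
    abort("unknown bad channel")
  }
  n_good <- nrow(m) - length(bad)
  if (n_good < 4) abort("too many bad channels to interpolate")
  pos <- montage_positions(montage)
  pos <- pos / sqrt(rowSums(pos^2))
  good <- setdiff(seq_len(nrow(m)), bad)
  cosang <- tcrossprod(pos)                 # cos of inter-electrode angles
  cosang <- pmin(pmax(cosang, -1), 1)
  G <- matrix(spline_g(as.vector(cosang[good, good])), n_good, n_good)
  Gb <- matrix(spline_g(as.vector(cosang[bad, good, drop = FALSE])),
               length(bad), n_good)
  # solve [G 1; 1' 0] [c; c0] = [v; 0] for each sample
  A <- rbind(cbind(G, 1), c(rep(1, n_good), 0))
  rhs <- rbind(m[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  est <- Gb %*% sol[seq_len(n_good), , drop = FALSE] +
    matrix(sol[n_good + 1L, ], length(bad), ncol(m), byrow = TRUE)
  m[bad, ] <- est
  m
}

#' Average kept epochs into an evoked dataset
#'
#' Arithmetic mean over epochs for every subject x condition cell, recording
#' the number of epochs used. Averages are re-referenced to the common
#' average (a no-op when the epochs already are).
#'
#' @param clean_list list of cleaned [epoched_eeg()] objects covering all
#'   four design cells for every subject.
#' @return an [evoked_dataset()].
#' @export
average_epochs <- function(clean_list) {
  stopifnot(length(clean_list) > 0)
  evoked <- list()
  n_used <- list()
  for (ep in clean_list) {
    if (dim(ep$data)[1] < 1) {
      abort(sprintf("no epochs for subject %s, condition %s",
                    ep$subject, ep$condition))
    }
    avg <- colMeans(ep$data)          # over epochs: channels x samples
    evoked[[ep$subject]][[ep$condition]] <- average_reference(avg)
    n_used[[length(n_used) + 1L]] <- tibble::tibble(
      subject = ep$subject, condition = ep$condition,
      n_epochs = dim(ep$data)[1])
  }
  first <- clean_list[[1]]
  evoked_dataset(evoked, dplyr::bind_rows(n_used), first$sfreq, first$t0,
                 first$montage)
}
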