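#' Dipole source configuration for the synthetic SEP study
#'
#' Describes the ground-truth generators of a simulated somatosensory
#' evoked potential study: each dipole has a source-space node, an
#' orientation, and a Gaussian amplitude time course (peak nAm at a given
#' latency and width). Per design cell, each dipole's amplitude may be
#' scaled by a gain, which is how condition effects are planted (the
#' default scenario modulates a right-posterior "parietal" dipole by
#' congruency, mimicking stronger parietal sources when visual feedback is
#' spatially congruent). Between-subject variability enters as one
#' multiplicative gain and one latency shift per subject (drawn once per
#' subject, not per epoch, consistent with evoked averaging).
#'
#' @param dipoles list of dipole specs: each a list with `node` (source
#'   node index), `orientation` (3-vector, normalized internally),
#'   `latency_ms`, `width_ms`, `peak_nam`.
#' @param cell_gains named list mapping condition names to numeric vectors
#'   (one gain per dipole); cells not named get gain 1 for every dipole.
#' @param subject_gain_sd SD of the per-subject multiplicative gain
#'   (mean 1, truncated at 0.1).
#' @param latency_jitter_sd_ms SD of the per-subject latency shift.
#' @return list of class `source_config`.
#' @export
source_config <- function(dipoles, cell_gains = list(),
                          subject_gain_sd = 0.1,
                          latency_jitter_sd_ms = 2) {
  stopifnot(length(dipoles) >= 1)
  for (d in dipoles) {
    stopifnot(is_count(d$node), is_number(d$latency_ms),
              is_number(d$width_ms), d$width_ms > 0,
              is_number(d$peak_nam), d$peak_nam > 0,
              length(d$orientation) == 3)
  }
  for (g in cell_gains) {
    stopifnot(length(g) == length(dipoles), all(g > 0))
  }
  structure(list(dipoles = dipoles, cell_gains = cell_gains,
                 subject_gain_sd = subject_gain_sd,
                 latency_jitter_sd_ms = latency_jitter_sd_ms),
            class = "source_config")
}

#' Noise configuration for simulated epochs
#'
#' @param sensor_sd_uv white sensor noise SD per channel/sample (uV).
#' @param spatial_sd_uv SD of the spatially correlated background (uV);
#'   drawn with an exponential spatial covariance over electrode distance.
#' @param spatial_scale correlation length on the unit sphere (chord
#'   distance) for the background.
#' @param artifact_rate fraction of epochs receiving a large-amplitude
#'   artifact (exercises the +/-20 uV rejection rule).
#' @param artifact_uv artifact amplitude (uV).
#' @return list of class `noise_config`.
#' @export
noise_config <- function(sensor_sd_uv = 4, spatial_sd_uv = 2,
                         spatial_scale = 0.8, artifact_rate = 0.02,
                         artifact_uv = 80) {
  stopifnot(sensor_sd_uv >= 0, spatial_sd_uv >= 0, spatial_scale > 0,
            artifact_rate >= 0, artifact_rate <= 1, artifact_uv >= 0)
  structure(list(sensor_sd_uv = sensor_sd_uv, spatial_sd_uv = spatial_sd_uv,
                 spatial_scale = spatial_scale, artifact_rate = artifact_rate,
                 artifact_uv = artifact_uv),
            class = "noise_config")
}

# Gaussian pulse s(t), t in seconds, latency/width in ms. Width is the
# Gaussian sigma.
gauss_pulse <- function(t, latency_ms, width_ms) {
  exp(-0.5 * ((t * 1000 - latency_ms) / width_ms)^2)
}

#' Simulate a multi-subject factorial evoked study
#'
#' Generates stimulus-locked epochs for `n_subjects` x 4 design cells:
#' each epoch is the lead-field projection of the configured dipole time
#' courses (with per-subject gain and latency jitter, and per-cell planted
#' gains) plus sensor and spatially correlated noise, with occasional
#' large artifacts. Everything is reproducible from `seed`; the returned
#' ground-truth record contains all per-subject draws and suffices to
#' rebuild every noiseless epoch.
#'
#' @param n_subjects number of subjects.
#' @param source_cfg a [source_config()].
#' @param noise_cfg a [noise_config()].
#' @param montage an [electrode_montage()].
#' @param lead a `lead_field` over the source space the dipole nodes index.
#' @param epochs_per_condition epochs per design cell (the full protocol
#'   delivers `stimulations_per_condition()` = 480).
#' @param sfreq sampling rate (default 512).
#' @param epoch_window epoch limits in s (default `c(-0.05, 0.3)`).
#' @param seed integer master seed.
#' @return list with `epochs` (list of [epoched_eeg()], one per subject x
#'   cell) and `truth` (ground-truth record: dipole table, per-cell gains,
#'   per-subject gains and latency shifts, seeds).
#' @export
simulate_evoked_study <- function(n_subjects, source_cfg, noise_cfg, montage,
                                  lead, epochs_per_condition = 480,
                                  sfreq = 512, epoch_window = c(-0.05, 0.3),
                                  seed = 1L) {
  stopifnot(is_count(n_subjects), inherits(source_cfg, "source_config"),
            inherits(noise_cfg, "noise_config"),
            inherits(lead, "lead_field"), is_count(epochs_per_condition))
  for (d in source_cfg$dipoles) {
    if (d$node > lead$n_nodes) {
      abort(sprintf("dipole node %d outside the %d-node source space",
                    d$node, lead$n_nodes))
    }
    if (d$latency_ms < epoch_window[1] * 1000 ||
        d$latency_ms >= epoch_window[2] * 1000) {
      abort(sprintf("dipole latency %g ms outside the epoch window",
                    d$latency_ms))
    }
  }
  setup <- study_setup(n_subjects, source_cfg, noise_cfg, montage, lead,
                       epochs_per_condition, sfreq, epoch_window, seed)
  epochs <- list()
  for (si in seq_len(n_subjects)) {
    for (cond in design_cells()$condition) {
      epochs[[length(epochs) + 1L]] <- simulate_cell_epochs(setup, si, cond)
    }
  }
  list(epochs = epochs, truth = setup$truth)
}

# Draw the per-subject parameters and precompute the deterministic pieces
# (scalp patterns, spatial noise factor) of a simulated study. The ground
# truth plus the master seed determine every epoch.
study_setup <- function(n_subjects, source_cfg, noise_cfg, montage, lead,
                        epochs_per_condition, sfreq, epoch_window, seed) {
  n_ch <- nrow(montage)
  t <- seq(epoch_window[1], epoch_window[2] - 1 / sfreq, by = 1 / sfreq)
  cells <- design_cells()$condition
  subjects <- sprintf("s%02d", seq_len(n_subjects))
  # per-dipole scalp pattern for a unit (1 nAm) moment
  patterns <- vapply(source_cfg$dipoles, function(d) {
    o <- d$orientation / sqrt(sum(d$orientation^2))
    cols <- 3L * (d$node - 1L) + 1:3
    as.numeric(lead$L[, cols] %*% o)
  }, numeric(n_ch))                          # n_ch x n_dipoles
  set.seed(derive_seed(seed, "subjects"))
  subj_gain <- pmax(0.1, rnorm(n_subjects, 1, source_cfg$subject_gain_sd))
  subj_shift_ms <- rnorm(n_subjects, 0, source_cfg$latency_jitter_sd_ms)
  # spatial covariance factor for correlated background
  pos <- montage_positions(montage)
  pos <- pos / sqrt(rowSums(pos^2))
  D <- as.matrix(stats::dist(pos))
  Rsp <- chol(exp(-D / noise_cfg$spatial_scale) + 1e-9 * diag(n_ch))
  gain_for <- function(cond) {
    g <- source_cfg$cell_gains[[cond]]
    if (is.null(g)) rep(1, length(source_cfg$dipoles)) else g
  }
  truth <- list(
    seed = as.integer(seed),
    subjects = subjects,
    dipoles = source_cfg$dipoles,
    cell_gains = lapply(stats::setNames(cells, cells), gain_for),
    subject_gain = subj_gain,
    subject_latency_shift_ms = subj_shift_ms,
    sfreq = sfreq, epoch_window = epoch_window,
    epochs_per_condition = as.integer(epochs_per_condition))
  list(truth = truth, source_cfg = source_cfg, noise_cfg = noise_cfg,
       montage = montage, patterns = patterns, Rsp = Rsp, t = t,
       gain_for = gain_for, seed = seed)
}

# Noiseless evoked waveform (channels x samples) for one subject x cell.
noiseless_evoked <- function(setup, si, cond) {
  tr <- setup$truth
  courses <- vapply(setup$source_cfg$dipoles, function(d) {
    d$peak_nam * gauss_pulse(setup$t,
                             d$latency_ms + tr$subject_latency_shift_ms[si],
                             d$width_ms)
  }, numeric(length(setup$t)))               # n_t x n_dipoles
  setup$patterns %*% (t(courses) * (tr$subject_gain[si] * setup$gain_for(cond)))
}

# Simulate the raw epochs of one subject x condition cell. Used cell by
# cell by the pipeline so a full-size study never has to sit in memory.
simulate_cell_epochs <- function(setup, si, cond) {
  tr <- setup$truth
  nz <- setup$noise_cfg
  n_ch <- nrow(setup$montage)
  n_t <- length(setup$t)
  n_ep <- tr$epochs_per_condition
  signal <- noiseless_evoked(setup, si, cond)
  set.seed(derive_seed(setup$seed, paste0("noise_", tr$subjects[si], "_", cond)))
  a <- array(0, c(n_ep, n_ch, n_t))
  for (e in seq_len(n_ep)) {
    eps <- matrix(rnorm(n_ch * n_t, 0, nz$sensor_sd_uv), n_ch, n_t)
    if (nz$spatial_sd_uv > 0) {
      eps <- eps + nz$spatial_sd_uv *
        crossprod(setup$Rsp, matrix(rnorm(n_ch * n_t), n_ch, n_t))
    }
    m <- signal + eps
    if (nz$artifact_rate > 0 && runif(1) < nz$artifact_rate) {
      ch <- sample.int(n_ch, 1)
      at <- sample.int(n_t, 1)
      span <- at:min(n_t, at + round(0.02 * tr$sfreq))
      m[ch, span] <- m[ch, span] + nz$artifact_uv
    }
    a[e, , ] <- m
  }
  epoched_eeg(a, tr$sfreq, tr$epoch_window[1], tr$subjects[si], cond,
              setup$montage)
}

#' Behavioral generating configuration
#'
#' Per-cell means and SDs for the questionnaire ratings (truncated to
#' `[0, 10]`) and the kinematic summaries (truncated at 0). Defaults mirror
#' the study conditions this generator emulates: a strong sense of agency
#' only without visuo-motor conflict (planted main effects of congruency
#' and synchrony, no interaction), flat control-question ratings, a
#' trajectory norm around 10.6 cm and velocity around 6.7 cm/s with a small
#' congruency x synchrony interaction on the trajectory norm.
#'
#' @param agency_mean,agency_sd named numeric vectors over the four cells.
#' @param control_mean,control_sd idem for the control question.
#' @param trajectory_mean_cm,trajectory_sd_cm idem, trajectory norm (cm).
#' @param velocity_mean_cm_s,velocity_sd_cm_s idem, mean velocity (cm/s).
#' @return list of class `behavioral_config`.
#' @export
behavioral_config <- function(
    agency_mean = c(congruent_synchronous = 7.5, congruent_asynchronous = 5.5,
                    incongruent_synchronous = 5.5,
                    incongruent_asynchronous = 3.5),
    agency_sd = rep_cells(1),
    control_mean = rep_cells(3), control_sd = rep_cells(1.5),
    trajectory_mean_cm = c(congruent_synchronous = 10.8,
                           congruent_asynchronous = 10.8,
                           incongruent_synchronous = 10.1,
                           incongruent_asynchronous = 10.8),
    trajectory_sd_cm = rep_cells(1.9),
    velocity_mean_cm_s = rep_cells(6.7),
    velocity_sd_cm_s = rep_cells(0.95)) {
  cells <- design_cells()$condition
  as_cells <- function(x) {
    if (length(x) == 1) x <- stats::setNames(rep(x, 4), cells)
    stopifnot(all(cells %in% names(x)))
    x[cells]
  }
  cfg <- list(
    agency_mean = as_cells(agency_mean), agency_sd = as_cells(agency_sd),
    control_mean = as_cells(control_mean), control_sd = as_cells(control_sd),
    trajectory_mean_cm = as_cells(trajectory_mean_cm),
    trajectory_sd_cm = as_cells(trajectory_sd_cm),
    velocity_mean_cm_s = as_cells(velocity_mean_cm_s),
    velocity_sd_cm_s = as_cells(velocity_sd_cm_s))
  stopifnot(all(cfg$agency_mean >= 0), all(cfg$agency_mean <= 10),
            all(cfg$control_mean >= 0), all(cfg$control_mean <= 10))
  structure(cfg, class = "behavioral_config")
}

rep_cells <- function(x) stats::setNames(rep(x, 4), design_cells()$condition)

# Truncated-normal draw on [lo, hi] by inverse-CDF; SD 0 returns the mean.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Simulate the behavioral outcome table
#'
#' Truncated-normal draws per subject x cell for the agency and control
#' ratings (bounded to the 0-10 scale) and the kinematic summaries
#' (bounded below by 0), reproducible from `seed`.
#'
#' @param n_subjects number of subjects.
#' @param cfg a [behavioral_config()].
#' @param missing_control subjects (indices) whose control rating is set to
#'   NA, emulating missing questionnaire reports.
#' @param seed integer seed.
#' @return a [behavioral_table()] with one row per subject x condition.
#' @export
simulate_behavior <- function(n_subjects, cfg = behavioral_config(),
                              missing_control = integer(), seed = 1L) {
  stopifnot(is_count(n_subjects), inherits(cfg, "behavioral_config"))
  cells <- design_cells()
  subjects <- sprintf("s%02d", seq_len(n_subjects))
  set.seed(derive_seed(seed, "behavior"))
  rows <- purrr::map_dfr(seq_len(nrow(cells)), function(ci) {
    cond <- cells$condition[ci]
    tibble::tibble(
      subject = subjects, condition = cond,
      congruency = cells$congruency[ci], synchrony = cells$synchrony[ci],
      agency_rating = rtruncnorm(n_subjects, cfg$agency_mean[[cond]],
                                 cfg$agency_sd[[cond]], 0, 10),
      control_rating = rtruncnorm(n_subjects, cfg$control_mean[[cond]],
                                  cfg$control_sd[[cond]], 0, 10),
      trajectory_norm_cm = rtruncnorm(n_subjects,
                                      cfg$trajectory_mean_cm[[cond]],
                                      cfg$trajectory_sd_cm[[cond]], 0, Inf),
      velocity_cm_s = rtruncnorm(n_subjects, cfg$velocity_mean_cm_s[[cond]],
                                 cfg$velocity_sd_cm_s[[cond]], 0, Inf))
  })
  if (length(missing_control)) {
    rows$control_rating[rows$subject %in% subjects[missing_control]] <- NA
  }
  behavioral_table(dplyr::arrange(rows, .data$subject, .data$condition))
}

#' Simulate hand trajectories for the kinematic feature extractor
#'
#' Continuous left-right sinusoidal hand movement over a 15 s trial,
#' sampled at `rate` Hz, with optional positional noise: x(t) =
#' amplitude * sin(2 pi f t) plus noise, y(t) = noise. The peak-to-peak
#' excursion (2 * amplitude) is the planted per-sweep trajectory norm.
#'
#' @param amplitude_cm sinusoid amplitude (half the left-right excursion).
#' @param freq_hz movement frequency.
#' @param duration_s trial duration (default 15 s).
#' @param rate sampling rate (Hz).
#' @param noise_sd_cm positional noise SD.
#' @param seed integer seed.
#' @return tibble: t_s, x_cm, y_cm.
#' @export
simulate_trajectory <- function(amplitude_cm = 5.3, freq_hz = 0.4,
                                duration_s = 15, rate = 50,
                                noise_sd_cm = 0, seed = 1L) {
  set.seed(derive_seed(seed, "trajectory"))
  t <- seq(0, duration_s, by = 1 / rate)
  tibble::tibble(
    t_s = t,
    x_cm = amplitude_cm * sin(2 * pi * freq_hz * t) +
      rnorm(length(t), 0, noise_sd_cm),
    y_cm = rnorm(length(t), 0, noise_sd_cm))
}
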