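#' The 2x2 visuo-motor conflict design
#'
#' The four within-subject cells crossing spatial congruency of the visual
#' feedback (congruent/incongruent) with its temporal synchrony
#' (synchronous/asynchronous).
#'
#' @return tibble with columns condition, congruency, synchrony.
#' @export
design_cells <- function() {
  tibble::tibble(
    congruency = rep(c("congruent", "incongruent"), each = 2),
    synchrony = rep(c("synchronous", "asynchronous"), 2)
  ) |>
    dplyr::mutate(condition = paste(.data$congruency, .data$synchrony, sep = "_"),
                  .before = 1)
}

#' Epoched EEG container
#'
#' Holds stimulus-locked epochs for one subject and condition as a 3-d array
#' `epochs x channels x samples` in microvolts, with sampling metadata and a
#' reference to the montage.
#'
#' @param data numeric array (epochs x channels x samples), potentials in uV.
#' @param sfreq sampling rate, samples/s.
#' @param t0 epoch start relative to stimulus onset, seconds (negative =
#'   pre-stimulus). Default -0.05.
#' @param subject subject identifier.
#' @param condition condition identifier (one of [design_cells()] or any
#'   label).
#' @param montage an [electrode_montage()]; channel count must match dim 2.
#' @return an object of class `epoched_eeg`.
#' @export
epoched_eeg <- function(data, sfreq, t0 = -0.05, subject = "s01",
                        condition = "congruent_synchronous", montage) {
  if (length(dim(data)) != 3) abort("`data` must be epochs x channels x samples")
  if (!all(is.finite(data))) abort("epoch data must be finite")
  stopifnot(is_number(sfreq), sfreq > 0, is_number(t0))
  if (nrow(montage) != dim(data)[2]) {
    abort(sprintf("montage has %d channels but data has %d",
                  nrow(montage), dim(data)[2]))
  }
  structure(
    list(data = data, sfreq = sfreq, t0 = t0,
         subject = as.character(subject), condition = as.character(condition),
         montage = montage),
    class = "epoched_eeg"
  )
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat_line(sprintf(
    "<epoched_eeg> subject %s, condition %s: %d epochs x %d channels x %d samples @ %g Hz, t0 = %g s",
    x$subject, x$condition, d[1], d[2], d[3], x$sfreq, x$t0))
  invisible(x)
}

#' Time axis of an epoched or evoked container
#' @param x an `epoched_eeg` or `evoked_dataset`.
#' @return numeric vector of sample times in seconds relative to stimulus.
#' @export
time_axis <- function(x) {
  n <- if (inherits(x, "epoched_eeg")) dim(x$data)[3] else x$n_samples
  x$t0 + (seq_len(n) - 1L) / x$sfreq
}

#' Evoked (averaged) dataset over a full factorial design
#'
#' Stores per-subject, per-condition average waveforms (channels x samples,
#' uV), the number of epochs entering each average, and the design labels.
#' All waveforms must be average-referenced: the spatial mean across
#' channels is ~0 at every sample.
#'
#' @param evoked named list: `evoked[[subject]][[condition]]` is a channels x
#'   samples matrix.
#' @param n_epochs_used tibble (subject, condition, n_epochs) or NULL.
#' @param sfreq sampling rate (samples/s).
#' @param t0 epoch start time (s).
#' @param montage an [electrode_montage()].
#' @param check if TRUE (default), enforce design completeness and average
#'   reference.
#' @return an object of class `evoked_dataset`.
#' @export
evoked_dataset <- function(evoked, n_epochs_used = NULL, sfreq, t0 = -0.05,
                           montage, check = TRUE) {
  subjects <- names(evoked)
  cells <- design_cells()$condition
  n_samples <- NULL
  for (s in subjects) {
    if (check && !all(cells %in% names(evoked[[s]]))) {
      missing <- setdiff(cells, names(evoked[[s]]))
      abort(sprintf("subject %s is missing design cell(s): %s",
                    s, paste(missing, collapse = ", ")))
    }
    for (cond in names(evoked[[s]])) {
      m <- evoked[[s]][[cond]]
      if (!is.matrix(m) || nrow(m) != nrow(montage)) {
        abort(sprintf("evoked[[%s]][[%s]] must be a %d x samples matrix",
                      s, cond, nrow(montage)))
      }
      n_samples <- n_samples %||% ncol(m)
      if (ncol(m) != n_samples) abort("all evoked waveforms must share a time base")
      if (check) {
        scale <- max(abs(m), 1e-30)
        if (max(abs(colMeans(m))) > 1e-9 * scale) {
          abort(sprintf(
            "evoked[[%s]][[%s]] is not average-referenced (max |spatial mean| = %.3g)",
            s, cond, max(abs(colMeans(m)))))
        }
      }
    }
  }
  structure(
    list(evoked = evoked, n_epochs_used = n_epochs_used, sfreq = sfreq,
         t0 = t0, montage = montage, n_samples = n_samples,
         subjects = subjects, conditions = cells),
    class = "evoked_dataset"
  )
}

#' @export
print.evoked_dataset <- function(x, ...) {
  cat_line(sprintf(
    "<evoked_dataset> %d subjects x %d conditions, %d channels x %d samples @ %g Hz",
    length(x$subjects), length(x$conditions), nrow(x$montage), x$n_samples,
    x$sfreq))
  invisible(x)
}

#' Re-reference a matrix of potentials to the common average
#'
#' Subtracts the instantaneous spatial mean from every sample so the mean
#' over channels is exactly zero.
#'
#' @param m channels x samples matrix (uV).
#' @return matrix of the same shape with zero column means.
#' @export
average_reference <- function(m) {
  sweep(m, 2, colMeans(m), "-")
}

#' Validate a behavioral outcome table
#'
#' A behavioral table holds one row per subject x condition with the
#' questionnaire ratings (0-10) and kinematic summaries (non-negative).
#' Missing ratings are allowed (recorded as NA and excluded listwise by the
#' analyses that use them).
#'
#' @param tbl data frame with columns subject, condition and at least one of
#'   agency_rating, control_rating, trajectory_norm_cm, velocity_cm_s.
#' @return the validated tibble, classed `behavioral_table`.
#' @export
behavioral_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  stopifnot(all(c("subject", "condition") %in% names(tbl)))
  for (col in intersect(c("agency_rating", "control_rating"), names(tbl))) {
    v <- tbl[[col]]
    bad <- !is.na(v) & (v < 0 | v > 10)
    if (any(bad)) {
      abort(sprintf("%s outside [0, 10] for subject(s): %s", col,
                    paste(unique(tbl$subject[bad]), collapse = ", ")))
    }
  }
  for (col in intersect(c("trajectory_norm_cm", "velocity_cm_s"), names(tbl))) {
    v <- tbl[[col]]
    if (any(!is.na(v) & v < 0)) abort(sprintf("%s must be non-negative", col))
  }
  class(tbl) <- unique(c("behavioral_table", class(tbl)))
  tbl
}
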