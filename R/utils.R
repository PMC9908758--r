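#' @importFrom rlang abort warn %||% .data
#' @importFrom stats sd var cor rnorm runif qnorm pnorm pt cor.test t.test
#' @importFrom utils head tail
NULL

# Deterministic child seed from a master seed and a stage label.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- digest::digest(list(as.integer(seed), as.character(label)), algo = "xxhash32")
  (strtoi(substr(h, 1, 7), base = 16L) %% 2147483629L) + 1L
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Half-open sample index range [start, end) for a time window in seconds,
# given epoch start t0 (s) and sampling rate (samples/s). 0-based times,
# 1-based R indices returned.
window_to_samples <- function(window, t0, sfreq, n_samples) {
  i0 <- round((window[1] - t0) * sfreq)
  i1 <- round((window[2] - t0) * sfreq)
  if (i0 < 0 || i1 > n_samples || i1 <= i0) {
    abort(sprintf(
      "time window [%g, %g) s falls outside the epoch [%g, %g) s",
      window[1], window[2], t0, t0 + n_samples / sfreq
    ))
  }
  seq.int(i0 + 1L, i1)
}

#' Stimulations delivered per condition in a factorial stimulation protocol
#'
#' Computes how many stimulus-locked events each design cell accumulates over
#' a session: `rate_hz * trial_s` stimulations per trial, times the number of
#' repetitions of the condition per block, times the number of blocks.
#' With the default protocol (2 Hz stimulation over 15 s trials, 4
#' repetitions per condition per block, 4 blocks) this gives 480.
#'
#' @param rate_hz stimulation rate in Hz.
#' @param trial_s trial duration in seconds.
#' @param trials_per_block repetitions of each condition within one block.
#' @param blocks number of blocks in the session.
#' @return integer count of stimulations per condition.
#' @export
#' @examples
#' stimulations_per_condition()
stimulations_per_condition <- function(rate_hz = 2, trial_s = 15,
                                       trials_per_block = 4, blocks = 4) {
  stopifnot(rate_hz > 0, trial_s > 0, is_count(trials_per_block), is_count(blocks))
  as.integer(round(rate_hz * trial_s)) * as.integer(trials_per_block) * as.integer(blocks)
}

cat_line <- function(...) cat(..., "\n", sep = "")
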