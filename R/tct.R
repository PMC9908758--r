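#' Topographic consistency test
#'
#' Permutation test for the presence of evoked activity at each time point,
#' run separately per condition. The observed statistic is the GFP of the
#' across-subject mean topography; if subjects share a common map, this
#' grand-average GFP exceeds what survives averaging of spatially
#' unaligned maps. The null is built by independently shuffling the
#' measured potentials across electrodes within each subject's topography
#' (which preserves every subject's own GFP exactly and only destroys
#' cross-subject spatial alignment), re-averaging, and recomputing the GFP.
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)`, so p can never
#' fall below `1/(n_permutations + 1)`.
#'
#' @param evoked an [evoked_dataset()] (average-referenced).
#' @param conditions conditions to test (default: all four cells).
#' @param n_permutations number of electrode shuffles per time point.
#' @param seed integer seed; the permutation stream is reproducible.
#' @return tibble of class `tct_result`: condition, time_ms, gfp_obs, p,
#'   with attributes `n_permutations` and `seed`.
#' @export
tct_test <- function(evoked, conditions = NULL, n_permutations = 1000,
                     seed = 1L) {
  conditions <- conditions %||% evoked$conditions
  if (length(evoked$subjects) < 2) {
    abort("the topographic consistency test needs at least 2 subjects")
  }
  stopifnot(is_count(n_permutations))
  n_ch <- nrow(evoked$montage)
  n_t <- evoked$n_samples
  times_ms <- time_axis(evoked) * 1000
  out <- vector("list", length(conditions))
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    # subjects x channels x time
    A <- array(0, c(length(evoked$subjects), n_ch, n_t))
    for (si in seq_along(evoked$subjects)) {
      A[si, , ] <- evoked$evoked[[evoked$subjects[si]]][[cond]]
    }
    n_sub <- dim(A)[1]
    obs <- gfp(colMeans(A))
    set.seed(derive_seed(seed, paste0("tct_", cond)))
    exceed <- integer(n_t)
    for (b in seq_len(n_permutations)) {
      # one independent electrode shuffle per subject, applied to all time
      # points of this draw
      M <- matrix(0, n_ch, n_t)
      for (si in seq_len(n_sub)) {
        M <- M + A[si, sample.int(n_ch), ]
      }
      null_g <- gfp(M / n_sub)
      exceed <- exceed + (null_g >= obs)
    }
    out[[ci]] <- tibble::tibble(
      condition = cond, time_ms = times_ms, gfp_obs = obs,
      p = (1 + exceed) / (1 + n_permutations))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_permutations") <- as.integer(n_permutations)
  attr(res, "seed") <- as.integer(seed)
  class(res) <- unique(c("tct_result", class(res)))
  res
}

#' Runs of consecutive topographic consistency
#'
#' Summarizes a [tct_test()] result into maximal runs of consecutive
#' significant time points per condition, so duration criteria can be
#' applied by the caller (no correction across time points is applied).
#'
#' @param tct a `tct_result`.
#' @param alpha significance level.
#' @return tibble: condition, start_ms, end_ms, n_samples.
#' @export
tct_runs <- function(tct, alpha = 0.05) {
  tct |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(d, key) {
      sig <- d$p < alpha
      r <- rle(sig)
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1L) + 1L)
      keep <- r$values
      dt <- if (nrow(d) > 1) diff(d$time_ms)[1] else 0
      tibble::tibble(start_ms = d$time_ms[starts[keep]],
                     end_ms = d$time_ms[ends[keep]] + dt,
                     n_samples = r$lengths[keep])
    }) |>
    dplyr::ungroup()
}
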