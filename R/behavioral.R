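#' Kinematic features of continuous hand trajectories
#'
#' The trial's principal movement axis is estimated as the direction of
#' maximal positional variance (first principal component). The projected
#' position is segmented into sweeps at direction reversals (sign changes
#' of the projected velocity); the trajectory norm is the Euclidean norm of
#' each sweep's displacement vector (start to end of the sweep, in the full
#' coordinate space), averaged over sweeps. Mean velocity is the total path
#' length divided by the trial duration. If no reversal is detected the
#' whole trial is one sweep (with a warning).
#'
#' @param traj data frame with column `t_s` (strictly increasing seconds)
#'   and two or more coordinate columns (cm), e.g. `x_cm`, `y_cm`.
#' @return tibble: trajectory_norm_cm, velocity_cm_s, n_sweeps.
#' @export
trajectory_features <- function(traj) {
  stopifnot("t_s" %in% names(traj), nrow(traj) >= 2)
  t <- traj$t_s
  if (any(diff(t) <= 0)) abort("timestamps must be strictly increasing")
  P <- as.matrix(traj[, setdiff(names(traj), "t_s"), drop = FALSE])
  duration <- t[length(t)] - t[1]
  steps <- diff(P)
  path_len <- sum(sqrt(rowSums(steps^2)))
  if (path_len == 0) {
    return(tibble::tibble(trajectory_norm_cm = 0, velocity_cm_s = 0,
                          n_sweeps = 0L))
  }
  # principal (left-right) axis by maximal positional variance
  axis <- stats::prcomp(P, center = TRUE, scale. = FALSE)$rotation[, 1]
  u <- as.numeric(P %*% axis)
  du <- diff(u)
  nz <- which(du != 0)
  s <- sign(du[nz])
  turns <- nz[which(diff(s) != 0)] + 1L   # sample index at each reversal
  if (length(turns) >= 2) {
    # full sweeps only: reversal to reversal (the lead-in before the first
    # reversal and the tail after the last are partial strokes)
    cuts <- turns
  } else {
    warn("no direction reversal detected; treating the trial as one sweep")
    cuts <- c(1L, nrow(P))
  }
  sweep_norms <- vapply(seq_len(length(cuts) - 1L), function(i) {
    sqrt(sum((P[cuts[i + 1L], ] - P[cuts[i], ])^2))
  }, numeric(1))
  tibble::tibble(trajectory_norm_cm = mean(sweep_norms),
                 velocity_cm_s = path_len / duration,
                 n_sweeps = length(sweep_norms))
}

#' Validate and assemble questionnaire ratings into an effect table
#'
#' Checks the 0-10 bounds, tolerates explicitly missing control-question
#' reports (NA), and returns the tidy subject x condition table the
#' permutation ANOVA consumes. Analyses that use a column drop subjects
#' with missing values listwise, so a table with two missing control
#' reports yields n-2 subjects for the control analysis and the full n for
#' agency.
#'
#' @param ratings data frame with subject, condition, agency_rating and
#'   optionally control_rating.
#' @return a [behavioral_table()] with congruency/synchrony columns added.
#' @export
questionnaire_table <- function(ratings) {
  stopifnot(all(c("subject", "condition", "agency_rating") %in%
                  names(ratings)))
  cells <- design_cells()
  out <- tibble::as_tibble(ratings) |>
    dplyr::select(-dplyr::any_of(c("congruency", "synchrony"))) |>
    dplyr::left_join(cells, by = "condition")
  if (any(is.na(out$congruency))) {
    abort(sprintf("unknown condition(s): %s",
                  paste(unique(out$condition[is.na(out$congruency)]),
                        collapse = ", ")))
  }
  behavioral_table(out)
}
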