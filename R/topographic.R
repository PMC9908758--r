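#' Global field power
#'
#' The spatial standard deviation (population convention, divisor N) of an
#' average-referenced potential map at one instant:
#' `sqrt(mean((u - mean(u))^2))`. GFP is reference-independent and indexes
#' the overall strength of the electric field.
#'
#' @param u numeric vector of potentials over channels (uV), or a channels x
#'   samples matrix (one GFP per column).
#' @return scalar (or vector, for a matrix input) in uV.
#' @export
#' @examples
#' gfp(c(1, -1))       # 1
#' gfp(rep(3, 64))     # 0
gfp <- function(u) {
  if (is.matrix(u)) {
    if (nrow(u) < 2) abort("GFP needs at least 2 channels")
    cu <- sweep(u, 2, colMeans(u), "-")
    return(sqrt(colMeans(cu^2)))
  }
  if (length(u) < 2) abort("GFP needs at least 2 channels")
  sqrt(mean((u - mean(u))^2))
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels of two average-referenced maps.
#' The sign is preserved: a map and its polarity inverse correlate at -1,
#' the convention for evoked (stimulus-locked) data where polarity carries
#' physiology.
#'
#' @param a,b numeric vectors over the same channels.
#' @return scalar in `[-1, 1]`.
#' @export
spatial_correlation <- function(a, b) {
  if (length(a) != length(b)) abort("topographies must share a montage")
  if (sd(a) == 0 || sd(b) == 0) {
    abort("spatial correlation undefined for a zero-variance topography")
  }
  as.numeric(cor(a, b))
}

# Internal: centered, unit-L2-norm versions of the columns of V.
# cor(u, v) across channels == crossprod of the normalized columns.
normalize_maps <- function(V) {
  cV <- sweep(V, 2, colMeans(V), "-")
  nrm <- sqrt(colSums(cV^2))
  if (any(nrm == 0)) abort("zero-variance topography in clustering input")
  sweep(cV, 2, nrm, "/")
}

#' Global explained variance of a labelled template assignment
#'
#' The GFP-weighted fraction of topographic variance captured by assigning
#' template map `labels[t]` to each time point:
#' `GEV = sum_t (GFP_t * r_t)^2 / sum_t GFP_t^2`, where `r_t` is the spatial
#' correlation between the data at `t` and its assigned template.
#'
#' @param V channels x time matrix of average-referenced topographies.
#' @param maps channels x q matrix of template maps.
#' @param labels integer vector (length = ncol(V)) of assigned map indices.
#' @return scalar in `[0, 1]`.
#' @export
gev <- function(V, maps, labels) {
  stopifnot(ncol(V) == length(labels), all(labels >= 1), all(labels <= ncol(maps)))
  g <- gfp(V)
  W <- normalize_maps(V)
  Mn <- normalize_maps(maps)
  r <- colSums(W * Mn[, labels, drop = FALSE])
  sum((g * r)^2) / sum(g^2)
}

#' Atomize-and-agglomerate hierarchical clustering of topographies
#'
#' AAHC starts from one cluster per time point and repeatedly removes
#' ("atomizes") the cluster contributing least to the global explained
#' variance, reassigning each orphaned time point to the remaining cluster
#' with the highest (signed) spatial correlation. A cluster's template is
#' the GFP-weighted mean of its member topographies, renormalized to unit
#' GFP; its contribution is `sum over members of (GFP_t * r_t)^2`.
#'
#' @param V channels x time matrix of average-referenced topographies
#'   (typically the group-average evoked of all conditions, concatenated).
#' @param q_range integer vector of cluster counts to record (default
#'   `1:min(12, T)`).
#' @return an object of class `aahc_hierarchy`: a list with one
#'   `template_map_set` per recorded q (named `"q<k>"`), each holding `q`,
#'   `maps` (channels x q, unit GFP), `labels`, `gev`, and `segments` (runs
#'   of constant label, half-open sample ranges).
#' @export
aahc_cluster <- function(V, q_range = NULL) {
  V <- as.matrix(V)
  Tn <- ncol(V)
  if (Tn < 1) abort("empty clustering input")
  q_range <- sort(unique(as.integer(q_range %||% seq_len(min(12L, Tn)))))
  if (any(q_range < 1) || any(q_range > Tn)) {
    abort("q_range must lie within [1, T]")
  }
  g <- gfp(V)
  W <- normalize_maps(V)          # channels x T, unit L2 columns
  gW <- sweep(V, 2, colMeans(V), "-")   # centered raw maps for templates
  denom <- sum(g^2)

  # state: cluster id per time point; per-cluster template (unit L2) and
  # contribution. Active clusters tracked by id.
  labels <- seq_len(Tn)
  templ <- W                       # start: each point is its own template
  contrib <- g^2                   # r = 1 with itself
  active <- rep(TRUE, Tn)
  solutions <- list()

  record <- function(labels, templ, active) {
    ids <- which(active)
    # order clusters by first member occurrence for stable output
    first <- vapply(ids, function(i) min(which(labels == i)), integer(1))
    ids <- ids[order(first)]
    relab <- match(labels, ids)
    q <- length(ids)
    # export maps at unit GFP: unit-L2 column * sqrt(N)
    maps <- templ[, ids, drop = FALSE] * sqrt(nrow(templ))
    colnames(maps) <- paste0("map", seq_len(q))
    r <- colSums(W * templ[, ids, drop = FALSE][, relab, drop = FALSE])
    structure(
      list(q = q, maps = maps, labels = relab,
           gev = sum((g * r)^2) / denom,
           segments = label_segments(relab)),
      class = "template_map_set")
  }

  recompute <- function(id, labels) {
    mem <- which(labels == id)
    m <- gW[, mem, drop = FALSE] %*% g[mem]      # GFP-weighted mean (unscaled)
    nrm <- sqrt(sum(m^2))
    if (nrm == 0) m <- W[, mem[1]] else m <- m / nrm
    r <- as.numeric(crossprod(W[, mem, drop = FALSE], m))
    list(template = as.numeric(m), contrib = sum((g[mem] * r)^2))
  }

  n_active <- Tn
  if (n_active %in% q_range) {
    solutions[[paste0("q", n_active)]] <- record(labels, templ, active)
  }
  while (n_active > max(1L, min(q_range))) {
    ids <- which(active)
    worst <- ids[which.min(contrib[ids])]
    mem <- which(labels == worst)
    active[worst] <- FALSE
    rest <- which(active)
    # reassign each orphan to the remaining cluster with highest signed corr
    rr <- crossprod(templ[, rest, drop = FALSE], W[, mem, drop = FALSE])
    newc <- rest[apply(rr, 2, which.max)]
    labels[mem] <- newc
    for (id in unique(newc)) {
      upd <- recompute(id, labels)
      templ[, id] <- upd$template
      contrib[id] <- upd$contrib
    }
    n_active <- n_active - 1L
    if (n_active %in% q_range) {
      solutions[[paste0("q", n_active)]] <- record(labels, templ, active)
    }
  }
  structure(list(solutions = solutions, q_range = q_range,
                 n_channels = nrow(V), n_time = Tn),
            class = "aahc_hierarchy")
}

label_segments <- function(labels) {
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  tibble::tibble(map = runs$values,
                 start = c(0L, head(ends, -1L)),   # half-open, 0-based
                 end = ends)
}

#' @export
print.aahc_hierarchy <- function(x, ...) {
  cat_line(sprintf("<aahc_hierarchy> %d channels x %d time points; q recorded: %s",
                   x$n_channels, x$n_time,
                   paste(x$q_range, collapse = ", ")))
  g <- vapply(x$solutions, `[[`, numeric(1), "gev")
  print(tibble::tibble(q = as.integer(sub("^q", "", names(g))), gev = g))
  invisible(x)
}

#' @export
print.template_map_set <- function(x, ...) {
  cat_line(sprintf("<template_map_set> q = %d, GEV = %.3f", x$q, x$gev))
  invisible(x)
}

#' Select the number of template maps
#'
#' The operative selector is the explained-variance rule: the smallest q
#' whose assignment reaches at least `gev_threshold` of the global explained
#' variance (default 90%). A Krzanowski-Lai style score on the
#' within-cluster dispersion of the normalized topographies is reported
#' alongside as an advisory diagnostic only.
#'
#' @param hierarchy an [aahc_cluster()] result.
#' @param V the clustering input matrix (needed for the KL dispersion).
#' @param gev_threshold explained-variance criterion in `[0, 1]`.
#' @return list with `q_star`, the selected `template_map_set`, and a
#'   tibble `criteria` (q, gev, W, kl).
#' @export
select_n_maps <- function(hierarchy, V, gev_threshold = 0.90) {
  qs <- hierarchy$q_range
  sols <- hierarchy$solutions[paste0("q", qs)]
  gevs <- vapply(sols, `[[`, numeric(1), "gev")
  Wn <- normalize_maps(as.matrix(V)) * sqrt(nrow(as.matrix(V)))  # unit GFP
  # within-cluster dispersion: sum over t of squared global map
  # dissimilarity between the unit-GFP map and its assigned template
  Wq <- vapply(sols, function(sol) {
    tn <- normalize_maps(sol$maps) * sqrt(nrow(sol$maps))
    d <- Wn - tn[, sol$labels, drop = FALSE]
    sum(colMeans(d^2))
  }, numeric(1))
  p <- hierarchy$n_channels
  diff_q <- rep(NA_real_, length(qs))
  for (i in seq_along(qs)) {
    j <- match(qs[i] - 1L, qs)
    if (!is.na(j)) {
      diff_q[i] <- (qs[i] - 1)^(2 / p) * Wq[j] - qs[i]^(2 / p) * Wq[i]
    }
  }
  kl <- rep(NA_real_, length(qs))
  for (i in seq_along(qs)) {
    j <- match(qs[i] + 1L, qs)
    if (!is.na(diff_q[i]) && !is.na(j) && !is.na(diff_q[j]) && diff_q[j] != 0) {
      kl[i] <- abs(diff_q[i] / diff_q[j])
    }
  }
  ok <- which(gevs >= gev_threshold)
  if (!length(ok)) {
    warn(sprintf("no q in range reaches GEV >= %g; returning the largest q",
                 gev_threshold))
    q_star <- max(qs)
  } else {
    q_star <- min(qs[ok])
  }
  list(q_star = q_star,
       templates = hierarchy$solutions[[paste0("q", q_star)]],
       criteria = tibble::tibble(q = qs, gev = unname(gevs), W = unname(Wq),
                                 kl = kl))
}

#' Fit template maps to single-subject evoked data
#'
#' Winner-take-all spatial-correlation fitting: within the analysis window,
#' each time point of each subject x condition waveform is assigned to the
#' template with the highest signed spatial correlation (ties broken by the
#' lowest map index). Per map the presence (duration in ms) and mean GFP
#' over the won samples are extracted; durations over maps sum exactly to
#' the window length.
#'
#' @param evoked an [evoked_dataset()].
#' @param templates a `template_map_set` (or a channels x q matrix).
#' @param window half-open analysis window `c(start_ms, end_ms)` relative to
#'   stimulus onset, in ms.
#' @return a tibble of class `fitting_result`: subject, condition,
#'   congruency, synchrony, map, n_samples, duration_ms, gfp_uv.
#' @export
fit_templates <- function(evoked, templates, window) {
  maps <- if (inherits(templates, "template_map_set")) templates$maps
          else as.matrix(templates)
  if (ncol(maps) < 1) abort("no template maps to fit")
  idx <- window_to_samples(window / 1000, evoked$t0, evoked$sfreq,
                           evoked$n_samples)
  Mn <- normalize_maps(maps)
  cells <- design_cells()
  rows <- list()
  for (s in evoked$subjects) {
    for (ci in seq_len(nrow(cells))) {
      cond <- cells$condition[ci]
      Vw <- evoked$evoked[[s]][[cond]][, idx, drop = FALSE]
      Wn <- normalize_maps(Vw)
      r <- crossprod(Mn, Wn)                     # q x n_samples
      win <- apply(r, 2, which.max)              # first max = lowest index
      gg <- gfp(Vw)
      for (k in seq_len(ncol(maps))) {
        won <- win == k
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = s, condition = cond,
          congruency = cells$congruency[ci], synchrony = cells$synchrony[ci],
          map = colnames(maps)[k] %||% paste0("map", k),
          n_samples = sum(won),
          duration_ms = sum(won) / evoked$sfreq * 1000,
          gfp_uv = if (any(won)) mean(gg[won]) else NA_real_)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "window") <- window
  attr(out, "sfreq") <- evoked$sfreq
  class(out) <- unique(c("fitting_result", class(out)))
  out
}

#' Select the analysis window from clustering, consistency and field strength
#'
#' Candidate windows are maximal runs over which the SET of template maps
#' in play across the conditions is constant (e.g., one map labelling the
#' congruent group averages and another the incongruent ones throughout the
#' stretch), intersected with the stretches of time that are
#' topographically consistent (TCT p < `alpha`) in every condition - the
#' analysis window is where a stable map configuration overlaps evoked
#' activity in all cells. The set, not the per-condition tuple, defines
#' stability: conditions may cross between the maps of the set a few
#' samples apart without breaking the period. Among these candidates, the
#' ones containing the global peak of the grand-average GFP are returned.
#'
#' @param labels_by_condition integer matrix, time x condition: the template
#'   label assigned to each post-stimulus sample of each condition's
#'   group-average waveform.
#' @param tct a `tct_result` (see [tct_test()]) on the same time base.
#' @param times_ms numeric vector of sample times (ms) for the rows of
#'   `labels_by_condition`.
#' @param alpha significance level for the consistency requirement.
#' @return tibble of class `window_selection` (start_ms, end_ms,
#'   has_gfp_peak, all_consistent), possibly empty (with a warning) when no
#'   sample is consistent in every condition.
#' @export
select_window <- function(labels_by_condition, tct, times_ms, alpha = 0.05) {
  L <- as.matrix(labels_by_condition)
  stopifnot(nrow(L) == length(times_ms))
  ptab <- tidyr::pivot_wider(tct[, c("condition", "time_ms", "p")],
                             names_from = "condition", values_from = "p")
  ptab <- ptab[match(round(times_ms, 6), round(ptab$time_ms, 6)), , drop = FALSE]
  P <- as.matrix(ptab[, setdiff(names(ptab), "time_ms"), drop = FALSE])
  consistent <- rowSums(P < alpha) == ncol(P)
  gfp_grand <- tct |>
    dplyr::group_by(.data$time_ms) |>
    dplyr::summarise(g = mean(.data$gfp_obs), .groups = "drop")
  gfp_grand <- gfp_grand$g[match(round(times_ms, 6), round(gfp_grand$time_ms, 6))]
  peak <- which.max(gfp_grand)
  key <- apply(L, 1, function(r) paste(sort(unique(r)), collapse = "|"))
  # run id per sample for the label set; a candidate is a maximal stretch
  # that is both within one run and consistent in every condition
  run_id <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  seg_key <- ifelse(consistent, run_id, NA_integer_)
  boundary <- c(TRUE, seg_key[-1] != seg_key[-length(seg_key)])
  boundary[is.na(boundary)] <- TRUE
  seg <- cumsum(boundary)
  ok <- which(consistent)
  dt <- if (length(times_ms) > 1) diff(times_ms)[1] else 1
  if (!length(ok)) {
    warn("no sample is topographically consistent in all conditions; empty window")
    out <- tibble::tibble(start_ms = numeric(), end_ms = numeric(),
                          all_consistent = logical(),
                          has_gfp_peak = logical())
  } else {
    cand <- tibble::tibble(seg = seg[ok], idx = ok) |>
      dplyr::group_by(.data$seg) |>
      dplyr::summarise(start = min(.data$idx), end = max(.data$idx),
                       .groups = "drop")
    out <- tibble::tibble(
      start_ms = times_ms[cand$start],
      end_ms = times_ms[cand$end] + dt,       # half-open
      all_consistent = TRUE,
      has_gfp_peak = peak >= cand$start & peak <= cand$end)
    out <- out[out$has_gfp_peak, , drop = FALSE]
    if (nrow(out) == 0) {
      warn("no stable consistent segment contains the GFP peak; empty window")
    }
  }
  class(out) <- unique(c("window_selection", class(out)))
  out
}
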