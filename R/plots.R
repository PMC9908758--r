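#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_hline geom_boxplot
#'   geom_point geom_tile facet_wrap labs theme_minimal scale_fill_gradient
#' @export
ggplot2::autoplot

#' Butterfly plot of an evoked dataset with the grand-average GFP
#'
#' One line per channel of the grand average (over subjects) per condition,
#' with the GFP overlaid.
#'
#' @param object an [evoked_dataset()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.evoked_dataset <- function(object, ...) {
  times <- time_axis(object) * 1000
  rows <- list()
  for (cond in object$conditions) {
    G <- Reduce(`+`, lapply(object$subjects,
                            function(s) object$evoked[[s]][[cond]])) /
      length(object$subjects)
    rows[[cond]] <- tibble::tibble(
      condition = cond,
      time_ms = rep(times, each = nrow(G)),
      channel = rep(object$montage$label, length(times)),
      uv = as.vector(G))
  }
  d <- dplyr::bind_rows(rows)
  gfp_d <- d |>
    dplyr::group_by(.data$condition, .data$time_ms) |>
    dplyr::summarise(uv = sqrt(mean((.data$uv - mean(.data$uv))^2)),
                     .groups = "drop")
  ggplot(d, aes(.data$time_ms, .data$uv, group = .data$channel)) +
    geom_line(alpha = 0.25, linewidth = 0.2) +
    geom_line(data = gfp_d, aes(group = NULL), color = "red",
              linewidth = 0.8) +
    facet_wrap(~condition) +
    labs(x = "time (ms)", y = "potential (uV)",
         title = "Grand-average evoked potentials (red: GFP)") +
    theme_minimal()
}

#' Consistency trace (1 - p) per condition
#'
#' Plots the topographic consistency test as 1 - p over time, one panel per
#' condition, with the significance level marked.
#'
#' @param object a `tct_result` from [tct_test()].
#' @param alpha significance level drawn as a reference line.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tct_result <- function(object, alpha = 0.05, ...) {
  ggplot(object, aes(.data$time_ms, 1 - .data$p)) +
    geom_line() +
    geom_hline(yintercept = 1 - alpha, linetype = "dashed", color = "red") +
    facet_wrap(~condition) +
    labs(x = "time (ms)", y = "1 - p",
         title = "Topographic consistency test") +
    theme_minimal()
}

#' Whisker plot of per-map durations by condition
#'
#' @param object a `fitting_result` from [fit_templates()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fitting_result <- function(object, ...) {
  ggplot(object, aes(.data$condition, .data$duration_ms)) +
    geom_boxplot(outlier.shape = NA) +
    geom_point(position = ggplot2::position_jitter(width = 0.1, seed = 1),
               alpha = 0.5, size = 1) +
    facet_wrap(~map) +
    labs(x = NULL, y = "map presence (ms)",
         title = "Template fitting: map duration by condition") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Template map topographies as interpolated scalp fields
#'
#' Projects each template map onto the 2-d scalp plane (azimuthal
#' projection of the electrode positions) and shows the potential at the
#' electrodes.
#'
#' @param templates a `template_map_set`.
#' @param montage the matching [electrode_montage()].
#' @return a ggplot.
#' @export
plot_template_maps <- function(templates, montage) {
  pos <- montage_positions(montage)
  pos <- pos / sqrt(rowSums(pos^2))
  # azimuthal equidistant projection from the vertex
  th <- acos(pmin(1, pmax(-1, pos[, 3])))
  r2 <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  px <- ifelse(r2 > 0, pos[, 1] / r2 * th, 0)
  py <- ifelse(r2 > 0, pos[, 2] / r2 * th, 0)
  d <- purrr::map_dfr(seq_len(templates$q), function(k) {
    tibble::tibble(map = colnames(templates$maps)[k],
                   x = px, y = py, uv = templates$maps[, k])
  })
  ggplot(d, aes(.data$x, .data$y, color = .data$uv)) +
    geom_point(size = 3) +
    ggplot2::scale_color_gradient2(low = "blue", mid = "white",
                                   high = "red") +
    ggplot2::coord_equal() +
    facet_wrap(~map) +
    labs(title = "Template maps (unit GFP)", color = "uV") +
    theme_minimal()
}

#' Current density by condition at selected nodes
#'
#' @param maps a `current_density_map` from [estimate_sources()].
#' @param nodes node ids to display (default: the 9 nodes with the highest
#'   grand-mean density).
#' @return a ggplot.
#' @export
plot_density_by_condition <- function(maps, nodes = NULL) {
  if (is.null(nodes)) {
    nodes <- maps |>
      dplyr::group_by(.data$node) |>
      dplyr::summarise(d = mean(.data$density), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$d)) |>
      dplyr::slice_head(n = 9) |>
      dplyr::pull(.data$node)
  }
  d <- maps[maps$node %in% nodes, ]
  ggplot(d, aes(.data$condition, .data$density)) +
    geom_boxplot() +
    facet_wrap(~node, scales = "free_y") +
    labs(x = NULL, y = "current density (nAm)",
         title = "Current density by condition") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
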