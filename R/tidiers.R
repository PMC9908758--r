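#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.perm_anova <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.perm_anova <- function(x, ...) {
  tibble::tibble(outcome = attr(x, "outcome"),
                 n_subjects = attr(x, "n_subjects"),
                 n_permutations = attr(x, "n_permutations"),
                 seed = attr(x, "seed"),
                 min_p = min(x$p))
}

#' @exportS3Method generics::tidy
tidy.tct_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.tct_result <- function(x, ...) {
  x |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_timepoints = dplyr::n(),
                     n_significant = sum(.data$p < 0.05),
                     min_p = min(.data$p), .groups = "drop") |>
    dplyr::mutate(n_permutations = attr(x, "n_permutations"),
                  seed = attr(x, "seed"))
}

#' @exportS3Method generics::tidy
tidy.fitting_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.fitting_result <- function(x, ...) {
  w <- attr(x, "window")
  tibble::tibble(window_start_ms = w[1], window_end_ms = w[2],
                 n_subjects = dplyr::n_distinct(x$subject),
                 n_maps = dplyr::n_distinct(x$map))
}

#' @exportS3Method generics::tidy
tidy.cluster_result <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x))
  out$nodes <- NULL
  out
}

#' @exportS3Method generics::glance
glance.cluster_result <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x),
                 n_significant = sum(x$significant),
                 largest = if (nrow(x)) max(x$size) else 0L,
                 threshold_p = attr(x, "threshold_p"),
                 min_size = attr(x, "min_size"))
}
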