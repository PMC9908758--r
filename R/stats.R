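# Observed repeated-measures 2x2 F statistics from within-subject contrasts.
# Y: n_subjects x 4 matrix, columns in design_cells() order
# (congruent_synchronous, congruent_asynchronous, incongruent_synchronous,
# incongruent_asynchronous). Each 1-df within-subject effect has
# F(1, n-1) = n * mean(c)^2 / var(c) with c the per-subject contrast score.
CONTRASTS_2X2 <- cbind(
  congruency = c(1, 1, -1, -1) / 2,
  synchrony = c(1, -1, 1, -1) / 2,
  `congruency:synchrony` = c(1, -1, -1, 1) / 2
)

rm_anova_f <- function(Y) {
  n <- nrow(Y)
  C <- Y %*% CONTRASTS_2X2                  # n x 3 contrast scores
  m <- colMeans(C)
  v <- colSums(sweep(C, 2, m, "-")^2) / (n - 1)
  f <- n * m^2 / v
  f[v == 0 & m == 0] <- 0                   # no effect, no error: define F = 0
  f
}

#' Permutation-based repeated-measures 2x2 ANOVA
#'
#' Observed F statistics come from the classical repeated-measures
#' decomposition (each 1-df effect tested against its subject-by-effect
#' interaction, df = (1, n-1)), computed through within-subject contrast
#' scores. The permutation null independently permutes the four cell values
#' within each subject (the global exchangeability null), recomputing all
#' three effects from each of the `n_permutations` resampled tables;
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`. Partial eta
#' squared is `SS_effect / (SS_effect + SS_error) = F / (F + n - 1)`.
#'
#' @param table data frame with columns subject, congruency, synchrony and
#'   the outcome; one row per subject x cell. Subjects with a missing
#'   outcome value in any cell are dropped listwise (with a message).
#' @param outcome name of the outcome column.
#' @param n_permutations default 10000 resamplings.
#' @param seed integer seed for the permutation stream.
#' @return object of class `perm_anova`: tibble (effect, df1, df2, F, p,
#'   eta_sq_p) with attributes n_subjects, n_permutations, seed, outcome.
#' @export
perm_rm_anova_2x2 <- function(table, outcome, n_permutations = 10000,
                              seed = 1L) {
  Y <- design_matrix_2x2(table, outcome)
  n <- nrow(Y)
  if (n < 3) abort("need at least 3 complete subjects")
  f_obs <- rm_anova_f(Y)
  set.seed(derive_seed(seed, paste0("anova_", outcome)))
  exceed <- c(0, 0, 0)
  for (b in seq_len(n_permutations)) {
    idx <- vapply(seq_len(n), function(i) sample.int(4L), integer(4))
    Yb <- matrix(Y[cbind(rep(seq_len(n), each = 4L), as.vector(idx))],
                 n, 4, byrow = TRUE)
    exceed <- exceed + (rm_anova_f(Yb) >= f_obs)
  }
  res <- tibble::tibble(
    effect = colnames(CONTRASTS_2X2),
    df1 = 1L, df2 = n - 1L,
    F = unname(f_obs),
    p = unname((1 + exceed) / (1 + n_permutations)),
    eta_sq_p = unname(f_obs / (f_obs + n - 1)))
  attr(res, "n_subjects") <- n
  attr(res, "n_permutations") <- as.integer(n_permutations)
  attr(res, "seed") <- as.integer(seed)
  attr(res, "outcome") <- outcome
  class(res) <- unique(c("perm_anova", class(res)))
  res
}

# Reshape a long effect table into the n x 4 cell matrix, dropping
# incomplete subjects listwise.
design_matrix_2x2 <- function(table, outcome) {
  stopifnot(all(c("subject", "congruency", "synchrony", outcome) %in%
                  names(table)))
  cells <- design_cells()
  wide <- table |>
    dplyr::mutate(cell = paste(.data$congruency, .data$synchrony, sep = "_")) |>
    dplyr::select("subject", "cell", dplyr::all_of(outcome)) |>
    tidyr::pivot_wider(names_from = "cell", values_from = dplyr::all_of(outcome))
  missing_cells <- setdiff(cells$condition, names(wide))
  if (length(missing_cells)) {
    abort(sprintf("incomplete design: missing cell(s) %s",
                  paste(missing_cells, collapse = ", ")))
  }
  Y <- as.matrix(wide[, cells$condition])
  rownames(Y) <- wide$subject
  complete <- stats::complete.cases(Y)
  if (!all(complete)) {
    message(sprintf("dropping %d subject(s) with missing %s: %s",
                    sum(!complete), outcome,
                    paste(wide$subject[!complete], collapse = ", ")))
  }
  Y[complete, , drop = FALSE]
}

#' Node-wise permutation 2x2 ANOVA over a current density map
#'
#' Runs the repeated-measures permutation ANOVA at every source node,
#' re-using one shared permutation schedule across nodes so the resulting
#' p-maps are spatially coherent (the same resampled designs are evaluated
#' everywhere).
#'
#' @param maps a `current_density_map` (see [estimate_sources()]).
#' @param n_permutations permutations in the shared schedule.
#' @param seed integer seed.
#' @return tibble of class `nodewise_anova`: node, effect, F, p, eta_sq_p.
#' @export
nodewise_anova <- function(maps, n_permutations = 5000, seed = 1L) {
  subjects <- unique(maps$subject)
  cells <- design_cells()$condition
  n <- length(subjects)
  if (n < 3) abort("need at least 3 subjects")
  n_nodes <- max(maps$node)
  # data cube: subjects x 4 cells x nodes
  A <- array(NA_real_, c(n, 4, n_nodes))
  for (si in seq_len(n)) {
    for (ci in seq_len(4)) {
      d <- maps[maps$subject == subjects[si] & maps$condition == cells[ci], ]
      A[si, ci, d$node] <- d$density
    }
  }
  if (anyNA(A)) abort("current density map is incomplete over the design")
  f_cube <- function(A) {
    # returns 3 x n_nodes matrix of F values
    vapply(seq_len(3), function(k) {
      w <- CONTRASTS_2X2[, k]
      C <- A[, 1, ] * w[1] + A[, 2, ] * w[2] + A[, 3, ] * w[3] + A[, 4, ] * w[4]
      m <- colMeans(C)
      v <- colSums(sweep(C, 2, m, "-")^2) / (n - 1)
      f <- n * m^2 / v
      f[v == 0 & m == 0] <- 0
      f
    }, numeric(n_nodes)) |> t()
  }
  f_obs <- f_cube(A)
  set.seed(derive_seed(seed, "nodewise"))
  schedule <- lapply(seq_len(n_permutations), function(b)
    vapply(seq_len(n), function(i) sample.int(4L), integer(4)))
  exceed <- matrix(0, 3, n_nodes)
  for (b in seq_len(n_permutations)) {
    idx <- schedule[[b]]
    Ab <- A
    for (si in seq_len(n)) Ab[si, , ] <- A[si, idx[, si], ]
    exceed <- exceed + (f_cube(Ab) >= f_obs)
  }
  p <- (1 + exceed) / (1 + n_permutations)
  out <- tibble::tibble(
    node = rep(seq_len(n_nodes), each = 3),
    effect = rep(colnames(CONTRASTS_2X2), n_nodes),
    F = as.vector(f_obs), p = as.vector(p),
    eta_sq_p = as.vector(f_obs / (f_obs + n - 1)))
  attr(out, "n_permutations") <- as.integer(n_permutations)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_subjects") <- n
  class(out) <- unique(c("nodewise_anova", class(out)))
  out
}

#' Spatial cluster-extent filter for node-wise p-maps
#'
#' Thresholds a per-node p-map at `threshold_p`, finds connected components
#' of the surviving nodes under the source-space adjacency, and flags as
#' statistically reliable only components of at least `min_size` contiguous
#' nodes (default 17). Sub-threshold components are reported but marked not
#' significant.
#'
#' @param p_by_node numeric vector of p-values, one per source node.
#' @param f_by_node numeric vector of F values (for cluster summaries).
#' @param space the [build_source_space()] defining contiguity.
#' @param threshold_p node-level threshold (default 0.05).
#' @param min_size minimum cluster extent in nodes (default 17).
#' @return tibble of class `cluster_result`: cluster, size, mean_F, peak_F,
#'   significant, nodes (list-column of member ids).
#' @export
spatial_cluster_filter <- function(p_by_node, f_by_node, space,
                                   threshold_p = 0.05, min_size = 17) {
  stopifnot(length(p_by_node) == space$n_nodes,
            length(f_by_node) == space$n_nodes)
  sig <- which(p_by_node < threshold_p)
  if (!length(sig)) {
    out <- tibble::tibble(cluster = integer(), size = integer(),
                          mean_F = numeric(), peak_F = numeric(),
                          significant = logical(), nodes = list())
    class(out) <- unique(c("cluster_result", class(out)))
    attr(out, "threshold_p") <- threshold_p
    attr(out, "min_size") <- min_size
    return(out)
  }
  edges <- do.call(rbind, lapply(sig, function(i) {
    nb <- intersect(space$neighbors[[i]], sig)
    nb <- nb[nb > i]
    if (length(nb)) cbind(i, nb) else NULL
  }))
  g <- igraph::graph_from_data_frame(
    d = if (is.null(edges)) data.frame(from = character(), to = character())
        else data.frame(from = as.character(edges[, 1]),
                        to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(sig)))
  comp <- igraph::components(g)
  membership <- comp$membership
  ids <- as.integer(names(membership))
  out <- tibble::tibble(node = ids, comp = as.integer(membership)) |>
    dplyr::group_by(.data$comp) |>
    dplyr::summarise(size = dplyr::n(),
                     mean_F = mean(f_by_node[.data$node]),
                     peak_F = max(f_by_node[.data$node]),
                     nodes = list(sort(.data$node)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size)) |>
    dplyr::mutate(cluster = dplyr::row_number(),
                  significant = .data$size >= min_size) |>
    dplyr::select("cluster", "size", "mean_F", "peak_F", "significant",
                  "nodes")
  attr(out, "threshold_p") <- threshold_p
  attr(out, "min_size") <- min_size
  class(out) <- unique(c("cluster_result", class(out)))
  out
}

#' Post-hoc paired contrasts with Cohen's d
#'
#' Two-sided paired t tests between named design cells, with the paired
#' effect size `d = mean(diff) / sd(diff)`. P-values are reported
#' uncorrected.
#'
#' @param table data frame with subject, condition and the outcome column.
#' @param outcome outcome column name.
#' @param contrasts list of 2-element character vectors of condition names;
#'   default compares all six cell pairs.
#' @return tibble: contrast, n, t, df, p, d, mean_diff.
#' @export
posthoc_paired <- function(table, outcome, contrasts = NULL) {
  conds <- unique(table$condition)
  contrasts <- contrasts %||% utils::combn(conds, 2, simplify = FALSE)
  purrr::map_dfr(contrasts, function(pr) {
    a <- table[table$condition == pr[1], c("subject", outcome)]
    b <- table[table$condition == pr[2], c("subject", outcome)]
    m <- dplyr::inner_join(a, b, by = "subject", suffix = c("_a", "_b"))
    m <- m[stats::complete.cases(m), ]
    diff <- m[[paste0(outcome, "_a")]] - m[[paste0(outcome, "_b")]]
    if (length(diff) < 2) abort("paired contrast needs >= 2 complete pairs")
    if (sd(diff) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(diff) - 1),
                 p.value = 1)
      d <- 0
    } else {
      tt <- t.test(m[[paste0(outcome, "_a")]], m[[paste0(outcome, "_b")]],
                   paired = TRUE)
      d <- mean(diff) / sd(diff)
    }
    tibble::tibble(contrast = paste(pr[1], "-", pr[2]), n = length(diff),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, d = d, mean_diff = mean(diff))
  })
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' @param x,y numeric vectors (n >= 3, both with positive variance).
#' @return tibble: r, t, df, p, n.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("Pearson correlation needs n >= 3")
  if (sd(x) == 0 || sd(y) == 0) abort("zero-variance input")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), t = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value, n = length(x))
}
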