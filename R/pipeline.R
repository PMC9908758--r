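#' Configuration for a full simulated study run
#'
#' Bundles every stage's parameters with the seeds and output location.
#' The defaults describe the emulated experiment: 10 subjects, a 2x2
#' congruency x synchrony within-subject design, 480 stimulations per
#' condition at 2 Hz, 64 channels at 512 Hz, epochs of -50 to +300 ms,
#' two dipole generators (left central, right posterior) with the
#' posterior one gained by 1.5 in the spatially congruent cells, and
#' behavioral tables with planted agency effects. `epochs_per_condition`,
#' permutation counts and the source grid can be scaled down for fast
#' replicated runs.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_subjects subjects in the simulated cohort.
#' @param epochs_per_condition epochs per design cell.
#' @param sfreq sampling rate (samples/s).
#' @param n_channels 64 for the standard 10-10 montage; any other value
#'   uses [montage_sphere()].
#' @param space_radius_mm,space_spacing_mm,connectivity source-grid
#'   geometry (the default 16 mm step keeps the inverse fast; set 2 mm for
#'   a full-resolution grid).
#' @param head_radius_mm scalp sphere radius for the analytic lead field.
#' @param congruent_gain planted amplitude gain of the posterior dipole in
#'   the congruent cells.
#' @param noise a [noise_config()].
#' @param behavior a [behavioral_config()].
#' @param missing_control subject indices with missing control ratings.
#' @param anova_permutations,tct_permutations,nodewise_permutations
#'   permutation counts for the three permutation tests.
#' @param q_range candidate map counts for clustering.
#' @param gev_threshold explained-variance criterion for map selection.
#' @param threshold_p,cluster_min_size node-level threshold and minimum
#'   cluster extent for the spatial filter.
#' @param out_dir if non-NULL, stage artifacts (CSV/JSON) are written here.
#' @return list of class `study_config`.
#' @export
study_config <- function(seed = 1L, n_subjects = 10,
                         epochs_per_condition = 480, sfreq = 512,
                         n_channels = 64, space_radius_mm = 70,
                         space_spacing_mm = 16, connectivity = 26,
                         head_radius_mm = 90, congruent_gain = 1.5,
                         noise = noise_config(),
                         behavior = behavioral_config(),
                         missing_control = c(4L, 9L),
                         anova_permutations = 10000,
                         tct_permutations = 1000,
                         nodewise_permutations = 5000,
                         q_range = 1:8, gev_threshold = 0.90,
                         threshold_p = 0.05, cluster_min_size = 17,
                         out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "study_config"
  cfg
}

nearest_node <- function(space, xyz) {
  which.min(colSums((t(space$nodes) - xyz)^2))
}

# The default generators: a left central "somatosensory" dipole peaking at
# 45 ms (P45-like), a right posterior "parietal" dipole at 40 ms, and a
# weaker polarity-reversed central source at 180 ms emulating the
# long-latency response (the emulated experiment showed two well-separated
# consistency windows, early and late). The congruency effect is planted
# as a rotation of the early mixture: in the congruent cells the parietal
# dipole is gained up (by `congruent_gain`) and the central one down, in
# the incongruent cells the reverse, chosen so the two condition
# topographies correlate only moderately (~0.7) while their field
# strengths stay close (GFP ratio ~1.1) - the planted effect is
# topographic, not a gross amplitude change.
default_sources <- function(space, congruent_gain) {
  r <- max(sqrt(rowSums(space$nodes^2)))
  left_central <- nearest_node(space, r * c(-0.45, -0.10, 0.70))
  right_post <- nearest_node(space, r * c(0.45, -0.60, 0.45))
  dip <- function(node, latency, width, peak, flip = 1) {
    o <- space$nodes[node, ] / sqrt(sum(space$nodes[node, ]^2))
    list(node = node, orientation = flip * o,
         latency_ms = latency, width_ms = width, peak_nam = peak)
  }
  source_config(
    dipoles = list(dip(left_central, 45, 8, 12),
                   dip(right_post, 40, 10, 6),
                   dip(left_central, 180, 20, 6, flip = -1)),
    cell_gains = list(
      congruent_synchronous = c(1 - (congruent_gain - 1) / 3,
                                congruent_gain, 1),
      congruent_asynchronous = c(1 - (congruent_gain - 1) / 3,
                                 congruent_gain, 1),
      incongruent_synchronous = c(1 + (congruent_gain - 1) / 3, 1, 1),
      incongruent_asynchronous = c(1 + (congruent_gain - 1) / 3, 1, 1)),
    subject_gain_sd = 0.1, latency_jitter_sd_ms = 2)
}

write_stage <- function(cfg, name, obj) {
  if (is.null(cfg$out_dir)) return(invisible(NULL))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(cfg$out_dir, name)
  if (is.data.frame(obj)) {
    utils::write.csv(obj, paste0(path, ".csv"), row.names = FALSE)
  } else {
    jsonlite::write_json(obj, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  invisible(NULL)
}

#' Run the full simulated evoked-potential study
#'
#' Executes the whole analysis in the canonical order: simulate epochs per
#' subject x cell (streamed, so memory stays flat) -> preprocess (filter,
#' reference, baseline, amplitude rejection) -> average -> topographic
#' clustering of the concatenated post-stimulus group averages -> map-count
#' selection (>= 90% explained variance) -> topographic consistency test
#' per condition -> analysis-window selection -> single-subject template
#' fitting and permutation ANOVA on map duration and GFP -> LAURA source
#' estimation over the window -> node-wise permutation ANOVA with the
#' spatial cluster filter -> behavioral tables with permutation ANOVAs,
#' post-hoc contrasts and the density/agency correlation.
#'
#' @param cfg a [study_config()].
#' @param progress print stage progress to stderr.
#' @return list of class `study_report` with each stage's outputs and a
#'   machine-readable `summary` list (also written as JSON when
#'   `cfg$out_dir` is set).
#' @export
run_study <- function(cfg = study_config(), progress = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  say <- function(...) if (progress) message(sprintf(...))
  t_start <- Sys.time()
  cfg_hash <- digest::digest(unclass(cfg))

  montage <- if (cfg$n_channels == 64) montage_1010_64() else
    montage_sphere(cfg$n_channels)
  space <- build_source_space(cfg$space_radius_mm, cfg$space_spacing_mm,
                              cfg$connectivity)
  lead <- leadfield_single_sphere(space, montage, cfg$head_radius_mm)
  src_cfg <- default_sources(space, cfg$congruent_gain)
  setup <- study_setup(cfg$n_subjects, src_cfg, cfg$noise, montage, lead,
                       cfg$epochs_per_condition, cfg$sfreq, c(-0.05, 0.3),
                       cfg$seed)
  say("simulating + preprocessing %d subjects x 4 cells", cfg$n_subjects)
  pp_cfg <- preproc_config(target_sfreq = cfg$sfreq)
  clean <- list()
  reports <- list()
  for (si in seq_len(cfg$n_subjects)) {
    for (cond in design_cells()$condition) {
      raw <- simulate_cell_epochs(setup, si, cond)
      pp <- preprocess_epochs(raw, pp_cfg)
      clean[[length(clean) + 1L]] <- pp$clean
      reports[[length(reports) + 1L]] <- pp$report
    }
  }
  rejection_report <- dplyr::bind_rows(reports)
  write_stage(cfg, "rejection_report", rejection_report)
  evoked <- average_epochs(clean)
  rm(clean)

  say("topographic clustering")
  post <- which(time_axis(evoked) >= 0)
  grand <- lapply(evoked$conditions, function(cond) {
    G <- Reduce(`+`, lapply(evoked$subjects,
                            function(s) evoked$evoked[[s]][[cond]])) /
      length(evoked$subjects)
    G[, post, drop = FALSE]
  })
  V <- do.call(cbind, grand)
  hier <- aahc_cluster(V, q_range = cfg$q_range)
  sel <- select_n_maps(hier, V, cfg$gev_threshold)
  templates <- sel$templates
  write_stage(cfg, "map_selection", sel$criteria)

  say("topographic consistency test")
  tct <- tct_test(evoked, n_permutations = cfg$tct_permutations,
                  seed = derive_seed(cfg$seed, "tct"))

  # per-condition labels of the post-stimulus group averages
  n_post <- length(post)
  labels_by_condition <- matrix(templates$labels, n_post, 4)
  times_ms <- time_axis(evoked)[post] * 1000
  tct_post <- tct[tct$time_ms >= 0, ]
  window_tbl <- select_window(labels_by_condition, tct_post, times_ms,
                              alpha = cfg$threshold_p)
  write_stage(cfg, "window_selection", window_tbl)
  have_window <- nrow(window_tbl) > 0
  window <- if (have_window) {
    as.numeric(window_tbl[which.max(window_tbl$end_ms - window_tbl$start_ms),
                          c("start_ms", "end_ms")])
  } else NULL

  fitting <- NULL
  duration_anova <- gfp_anova <- NULL
  sources <- node_tests <- clusters <- NULL
  density_correlation <- NULL
  if (have_window) {
    say("fitting templates over [%g, %g) ms", window[1], window[2])
    fitting <- fit_templates(evoked, templates, window)
    write_stage(cfg, "fitting", tidy(fitting))
    # the condition-defining map: modal label of the congruent group
    # averages within the window (the counterpart of the emulated study's
    # "map A")
    in_win <- times_ms >= window[1] & times_ms < window[2]
    lab_cong <- labels_by_condition[in_win, 1:2]
    map_a <- paste0("map", names(which.max(table(lab_cong))))
    fit_a <- fitting[fitting$map == map_a, ]
    duration_anova <- perm_rm_anova_2x2(
      fit_a, "duration_ms", cfg$anova_permutations,
      seed = derive_seed(cfg$seed, "duration"))
    attr(duration_anova, "outcome_map") <- map_a
    gfp_cell <- fitting |>
      dplyr::group_by(.data$subject, .data$condition, .data$congruency,
                      .data$synchrony) |>
      dplyr::summarise(
        gfp_uv = stats::weighted.mean(.data$gfp_uv, .data$n_samples,
                                      na.rm = TRUE),
        .groups = "drop")
    gfp_anova <- perm_rm_anova_2x2(gfp_cell, "gfp_uv",
                                   cfg$anova_permutations,
                                   seed = derive_seed(cfg$seed, "gfp"))
    write_stage(cfg, "duration_anova", tidy(duration_anova))
    write_stage(cfg, "gfp_anova", tidy(gfp_anova))

    say("source estimation + node-wise ANOVA (%d nodes)", space$n_nodes)
    inv <- build_laura_inverse(lead, space)
    sources <- estimate_sources(evoked, inv, window)
    node_tests <- nodewise_anova(sources, cfg$nodewise_permutations,
                                 seed = derive_seed(cfg$seed, "nodewise"))
    cong <- node_tests[node_tests$effect == "congruency", ]
    cong <- cong[order(cong$node), ]
    clusters <- spatial_cluster_filter(cong$p, cong$F, space,
                                       cfg$threshold_p, cfg$cluster_min_size)
    write_stage(cfg, "node_clusters", tidy(clusters))
  }

  say("behavioral analyses")
  behav <- simulate_behavior(cfg$n_subjects, cfg$behavior,
                             missing_control = cfg$missing_control,
                             seed = derive_seed(cfg$seed, "behavior"))
  write_stage(cfg, "behavioral_table", behav)
  behav_anovas <- list(
    agency = perm_rm_anova_2x2(behav, "agency_rating",
                               cfg$anova_permutations,
                               seed = derive_seed(cfg$seed, "agency")),
    control = perm_rm_anova_2x2(behav, "control_rating",
                                cfg$anova_permutations,
                                seed = derive_seed(cfg$seed, "control")),
    trajectory = perm_rm_anova_2x2(behav, "trajectory_norm_cm",
                                   cfg$anova_permutations,
                                   seed = derive_seed(cfg$seed, "trajectory")),
    velocity = perm_rm_anova_2x2(behav, "velocity_cm_s",
                                 cfg$anova_permutations,
                                 seed = derive_seed(cfg$seed, "velocity")))
  posthoc <- posthoc_paired(behav, "trajectory_norm_cm")

  if (!is.null(clusters) && any(clusters$significant)) {
    nodes <- clusters$nodes[[which(clusters$significant)[1]]]
    dens_diff <- sources |>
      dplyr::filter(.data$node %in% nodes) |>
      dplyr::group_by(.data$subject, .data$congruency) |>
      dplyr::summarise(d = mean(.data$density), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "congruency", values_from = "d") |>
      dplyr::mutate(diff = .data$congruent - .data$incongruent)
    soa_diff <- behav |>
      dplyr::group_by(.data$subject, .data$congruency) |>
      dplyr::summarise(a = mean(.data$agency_rating), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "congruency", values_from = "a") |>
      dplyr::mutate(diff = .data$congruent - .data$incongruent)
    m <- dplyr::inner_join(dens_diff[, c("subject", "diff")],
                           soa_diff[, c("subject", "diff")],
                           by = "subject", suffix = c("_dens", "_soa"))
    density_correlation <- pearson_correlation(m$diff_dens, m$diff_soa)
  }

  summary <- list(
    config_hash = cfg_hash, seed = cfg$seed,
    n_subjects = cfg$n_subjects,
    epochs_per_condition = cfg$epochs_per_condition,
    epochs_rejected_fraction = mean(!rejection_report$kept),
    q_star = sel$q_star, gev = templates$gev,
    window_ms = if (have_window) window else NULL,
    window_map = if (!is.null(duration_anova)) attr(duration_anova, "outcome_map") else NULL,
    duration_congruency_F = if (!is.null(duration_anova))
      duration_anova$F[duration_anova$effect == "congruency"] else NULL,
    duration_congruency_p = if (!is.null(duration_anova))
      duration_anova$p[duration_anova$effect == "congruency"] else NULL,
    gfp_min_p = if (!is.null(gfp_anova)) min(gfp_anova$p) else NULL,
    n_retained_clusters = if (!is.null(clusters))
      sum(clusters$significant) else 0L,
    largest_cluster_nodes = if (!is.null(clusters) && nrow(clusters))
      max(clusters$size) else 0L,
    agency_congruency_p =
      behav_anovas$agency$p[behav_anovas$agency$effect == "congruency"],
    agency_synchrony_p =
      behav_anovas$agency$p[behav_anovas$agency$effect == "synchrony"],
    control_min_p = min(behav_anovas$control$p),
    density_soa_r = if (!is.null(density_correlation))
      density_correlation$r else NULL,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  if (!is.null(cfg$out_dir)) {
    s <- summary
    s$elapsed_s <- NULL   # keep the summary file reproducible bit for bit
    jsonlite::write_json(s, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(
    list(config = cfg, truth = setup$truth, evoked = evoked,
         rejection_report = rejection_report, hierarchy = hier,
         selection = sel, templates = templates, tct = tct,
         window = window_tbl, fitting = fitting,
         duration_anova = duration_anova, gfp_anova = gfp_anova,
         sources = sources, node_tests = node_tests, clusters = clusters,
         behavior = behav, behavioral_anovas = behav_anovas,
         posthoc = posthoc, density_correlation = density_correlation,
         summary = summary),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  s <- x$summary
  cat_line("<study_report>")
  cat_line(sprintf("  subjects: %d, epochs/condition: %d (rejected %.1f%%)",
                   s$n_subjects, s$epochs_per_condition,
                   100 * s$epochs_rejected_fraction))
  cat_line(sprintf("  maps: q* = %d (GEV %.3f)", s$q_star, s$gev))
  if (!is.null(s$window_ms)) {
    cat_line(sprintf("  window: [%g, %g) ms", s$window_ms[1], s$window_ms[2]))
    cat_line(sprintf("  duration congruency: F = %.2f, p = %.4f",
                     s$duration_congruency_F, s$duration_congruency_p))
    cat_line(sprintf("  retained node clusters: %d (largest %d nodes)",
                     s$n_retained_clusters, s$largest_cluster_nodes))
  } else {
    cat_line("  no analysis window selected")
  }
  cat_line(sprintf("  agency: p(congruency) = %.4f, p(synchrony) = %.4f",
                   s$agency_congruency_p, s$agency_synchrony_p))
  invisible(x)
}
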