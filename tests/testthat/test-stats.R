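rand_design <- function(n, effect = 0) {
  d <- design_cells()[rep(1:4, n), ]
  d$subject <- rep(sprintf("s%02d", 1:n), each = 4)
  d$y <- rnorm(nrow(d)) + effect * (d$congruency == "congruent")
  d
}

test_that("observed repeated-measures F matches the aov oracle", {
  set.seed(1)
  for (i in 1:20) {
    tbl <- rand_design(sample(4:9, 1), effect = runif(1, 0, 2))
    res <- perm_rm_anova_2x2(tbl, "y", n_permutations = 5, seed = 1)
    expect_equal(unname(res$F), unname(aov_rm_f(tbl, "y")),
                 tolerance = 1e-10)
    expect_equal(res$eta_sq_p, res$F / (res$F + res$df2), tolerance = 1e-12)
  }
})

test_that("degenerate and invariance properties of the F statistic", {
  # identical cell values within each subject -> zero effects everywhere
  tbl <- rand_design(5)
  tbl$y <- rep(rnorm(5), each = 4)
  res <- perm_rm_anova_2x2(tbl, "y", n_permutations = 10, seed = 1)
  expect_equal(res$F, rep(0, 3))
  # adding a per-subject constant never changes F (within-subject design)
  set.seed(2)
  tbl2 <- rand_design(8, effect = 1)
  shifted <- tbl2
  shifted$y <- shifted$y + rep(rnorm(8, sd = 50), each = 4)
  f1 <- perm_rm_anova_2x2(tbl2, "y", 10, seed = 3)$F
  f2 <- perm_rm_anova_2x2(shifted, "y", 10, seed = 3)$F
  expect_equal(f1, f2, tolerance = 1e-9)
  # incomplete designs are rejected with the missing cells named
  expect_error(perm_rm_anova_2x2(tbl[tbl$condition !=
                                       "congruent_synchronous", ], "y"),
               "congruent_synchronous")
})

test_that("permutation p-values respect their floor and reproduce by seed", {
  set.seed(3)
  tbl <- rand_design(10, effect = 5)
  res <- perm_rm_anova_2x2(tbl, "y", n_permutations = 199, seed = 7)
  expect_true(all(res$p >= 1 / 200))
  expect_equal(res$p[res$effect == "congruency"], 1 / 200)
  res2 <- perm_rm_anova_2x2(tbl, "y", n_permutations = 199, seed = 7)
  expect_identical(res$p, res2$p)
})

test_that("a planted within-subject effect is detected with high power", {
  set.seed(4)
  hits <- 0
  for (r in 1:30) {
    tbl <- rand_design(10, effect = 1.2)   # standardized delta = 1.2
    res <- perm_rm_anova_2x2(tbl, "y", n_permutations = 199, seed = r)
    hits <- hits + (res$p[res$effect == "congruency"] <= 0.05)
  }
  expect_gte(hits / 30, 0.8)
})

test_that("node-wise ANOVA shares one permutation schedule and finds a
           planted node", {
  set.seed(5)
  mk_maps <- function(effect_node = NULL) {
    cells <- design_cells()
    rows <- purrr::map_dfr(sprintf("s%02d", 1:8), function(s) {
      purrr::map_dfr(1:4, function(ci) {
        dens <- abs(rnorm(12, 5, 1))
        if (!is.null(effect_node) &&
            cells$congruency[ci] == "congruent") {
          dens[effect_node] <- dens[effect_node] + 4
        }
        tibble::tibble(subject = s, condition = cells$condition[ci],
                       congruency = cells$congruency[ci],
                       synchrony = cells$synchrony[ci],
                       node = 1:12, density = dens)
      })
    })
    rows
  }
  flat <- mk_maps()
  flat$density <- rep(1:8, each = 48) + 0   # per-subject constant only
  res_flat <- nodewise_anova(flat, n_permutations = 20, seed = 1)
  expect_equal(res_flat$F, rep(0, nrow(res_flat)))
  m0 <- mk_maps()
  a <- nodewise_anova(m0, n_permutations = 50, seed = 2)
  b <- nodewise_anova(m0, n_permutations = 50, seed = 2)
  expect_identical(a$p, b$p)
  hits <- 0
  for (r in 1:10) {
    m <- mk_maps(effect_node = 7)
    res <- nodewise_anova(m, n_permutations = 99, seed = r)
    cong <- res[res$effect == "congruency", ]
    hits <- hits + (which.min(cong$p[order(cong$node)]) == 7)
  }
  expect_gte(hits, 9)
})

test_that("the 17-node cluster-extent rule reproduces the retained/dropped
           pattern and matches a flood-fill oracle", {
  # two planted components of 37 and 12 significant nodes: exactly one
  # survives the >= 17 contiguous-node threshold
  sp <- build_source_space(24, 4, 6)
  grow <- function(seed_node, size, avoid = integer()) {
    mem <- seed_node
    frontier <- seed_node
    while (length(mem) < size) {
      nxt <- setdiff(unique(unlist(sp$neighbors[frontier])), c(mem, avoid))
      take <- utils::head(nxt, size - length(mem))
      mem <- c(mem, take)
      frontier <- take
    }
    mem
  }
  c1 <- grow(which.min(sp$nodes[, 1]), 37)
  c2 <- grow(which.max(sp$nodes[, 1]), 12, avoid = c1)
  expect_length(intersect(c1, c2), 0)
  p <- rep(0.5, sp$n_nodes); p[c(c1, c2)] <- 0.01
  f <- seq_len(sp$n_nodes) / sp$n_nodes
  cl <- spatial_cluster_filter(p, f, sp, threshold_p = 0.05, min_size = 17)
  expect_equal(nrow(cl), 2)
  expect_equal(sum(cl$significant), 1)
  expect_equal(cl$size[cl$significant], 37)
  expect_equal(sort(cl$nodes[[which(cl$significant)]]), sort(c1))
  # empty result when nothing is significant
  cl0 <- spatial_cluster_filter(rep(0.9, sp$n_nodes), f, sp)
  expect_equal(nrow(cl0), 0)
  # random p-maps: component sizes match the BFS oracle
  set.seed(6)
  for (i in 1:20) {
    pm <- runif(sp$n_nodes)
    cl <- spatial_cluster_filter(pm, f, sp, threshold_p = 0.3, min_size = 5)
    oracle <- bfs_components(which(pm < 0.3), sp$neighbors)
    expect_setequal(vapply(cl$nodes, length, 0L),
                    vapply(oracle, length, 0L))
    expect_setequal(vapply(cl$nodes, paste, "", collapse = ","),
                    vapply(oracle, paste, "", collapse = ","))
  }
})

test_that("paired contrasts match the textbook formula and flip cleanly", {
  set.seed(7)
  tbl <- rand_design(4, effect = 0.5)
  ph <- posthoc_paired(tbl, "y",
                       contrasts = list(c("congruent_synchronous",
                                          "incongruent_synchronous")))
  a <- tbl$y[tbl$condition == "congruent_synchronous"]
  b <- tbl$y[tbl$condition == "incongruent_synchronous"]
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  p_hand <- 2 * pt(-abs(t_hand), 3)
  expect_equal(ph$t, t_hand, tolerance = 1e-10)
  expect_equal(ph$p, p_hand, tolerance = 1e-10)
  expect_equal(ph$d, mean(d) / sd(d), tolerance = 1e-10)
  flipped <- posthoc_paired(tbl, "y",
                            contrasts = list(c("incongruent_synchronous",
                                               "congruent_synchronous")))
  expect_equal(flipped$t, -ph$t, tolerance = 1e-12)
  expect_equal(flipped$d, -ph$d, tolerance = 1e-12)
  # identical pairs -> zero statistic and effect size
  tbl0 <- tbl; tbl0$y <- rep(rnorm(4), each = 4)
  ph0 <- posthoc_paired(tbl0, "y",
                        contrasts = list(c("congruent_synchronous",
                                           "congruent_asynchronous")))
  expect_equal(ph0$t, 0)
  expect_equal(ph0$d, 0)
})

test_that("Pearson correlation hits closed forms and the t-based p", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    res <- pearson_correlation(a, b)
    r_hand <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    t_hand <- r_hand * sqrt(8 / (1 - r_hand^2))
    expect_equal(res$r, r_hand, tolerance = 1e-12)
    expect_equal(res$p, 2 * pt(-abs(t_hand), 8), tolerance = 1e-12)
  }
  expect_error(pearson_correlation(1:2, 2:3), "n >= 3")
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "zero-variance")
})
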