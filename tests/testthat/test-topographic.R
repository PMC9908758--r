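test_that("GFP equals the population spatial standard deviation", {
  expect_equal(gfp(c(1, -1)), 1)
  expect_equal(gfp(rep(3.7, 64)), 0)
  set.seed(1)
  for (i in 1:100) {
    u <- rnorm(64) * 10^runif(1, -3, 3)
    expect_equal(gfp(u), sqrt(mean((u - mean(u))^2)), tolerance = 1e-12)
  }
  expect_error(gfp(1), "at least 2")
})

test_that("spatial correlation is a signed Pearson over channels", {
  set.seed(2)
  a <- rand_topo(32)
  expect_equal(spatial_correlation(a, a), 1)
  expect_equal(spatial_correlation(a, -a), -1)
  for (i in 1:100) {
    x <- rnorm(16); y <- rnorm(16)
    expect_equal(spatial_correlation(x, y),
                 sum((x - mean(x)) * (y - mean(y))) /
                   sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
                 tolerance = 1e-12)
  }
  expect_error(spatial_correlation(rep(1, 8), rnorm(8)), "zero-variance")
  expect_error(spatial_correlation(rnorm(4), rnorm(5)), "montage")
})

test_that("GEV matches brute-force summation and hits its closed forms", {
  set.seed(3)
  for (i in 1:100) {
    V <- rand_topo_series(4, 6)
    maps <- rand_topo_series(4, 3)
    lab <- sample(1:3, 6, replace = TRUE)
    num <- 0; den <- 0
    for (t in 1:6) {
      r <- cor(V[, t], maps[, lab[t]])
      num <- num + (gfp(V[, t]) * r)^2
      den <- den + gfp(V[, t])^2
    }
    expect_equal(gev(V, maps, lab), num / den, tolerance = 1e-12)
  }
  V <- rand_topo_series(8, 5)
  # templates = the data itself, one per time point -> GEV 1
  expect_equal(gev(V, V, 1:5), 1, tolerance = 1e-12)
  # an orthogonal map assigned everywhere -> GEV 0
  b <- rand_topo(8)
  v1 <- V[, 1]
  orth <- b - v1 * sum(b * v1) / sum(v1^2)
  expect_equal(gev(V[, 1, drop = FALSE], cbind(orth), 1), 0,
               tolerance = 1e-12)
})

test_that("AAHC recovers exact planted structure", {
  set.seed(4)
  A <- rand_topo(16); B <- rand_topo(16)
  B <- B - A * sum(A * B) / sum(A^2)          # orthogonal pair
  V <- cbind(2 * A, 1.5 * B, 0.8 * A, 2.2 * B, 1.1 * A, 0.9 * B)
  h <- aahc_cluster(V, q_range = 1:3)
  s2 <- h$solutions$q2
  expect_equal(s2$gev, 1, tolerance = 1e-12)
  expect_equal(s2$labels, c(1, 2, 1, 2, 1, 2))
  expect_equal(abs(cor(s2$maps[, 1], A)), 1, tolerance = 1e-10)
  expect_equal(abs(cor(s2$maps[, 2], B)), 1, tolerance = 1e-10)
  # T identical topographies -> q = 1 explains everything
  W <- matrix(A, 16, 7) * rep(runif(7, 0.5, 2), each = 16)
  h1 <- aahc_cluster(W, q_range = 1)
  expect_equal(h1$solutions$q1$gev, 1, tolerance = 1e-12)
  expect_error(aahc_cluster(matrix(0, 4, 0)), "empty|q_range")
})

test_that("every AAHC step matches the naive re-implementation", {
  set.seed(5)
  for (i in 1:10) {
    V <- rand_topo_series(4, 8)
    h <- aahc_cluster(V, q_range = 1:8)
    naive <- aahc_naive(V, 1:8)
    for (q in 1:8) {
      expect_identical(h$solutions[[paste0("q", q)]]$labels,
                       naive[[paste0("q", q)]])
    }
  }
})

test_that("GEV is non-decreasing in q along the hierarchy", {
  set.seed(6)
  for (i in 1:10) {
    V <- rand_topo_series(8, 30)
    h <- aahc_cluster(V, q_range = 1:10)
    gevs <- vapply(paste0("q", 1:10),
                   function(k) h$solutions[[k]]$gev, 0)
    expect_true(all(diff(gevs) >= -1e-12))
  }
})

test_that("map-count selection applies the 90% explained-variance rule", {
  set.seed(7)
  A <- rand_topo(16); B <- rand_topo(16)
  B <- B - A * sum(A * B) / sum(A^2)
  V <- cbind(A, B, A, B, A, B) * rep(runif(6, 0.8, 1.2), each = 16)
  h <- aahc_cluster(V, q_range = 1:4)
  sel <- select_n_maps(h, V, 0.90)
  expect_equal(sel$q_star, 2)
  expect_named(sel$criteria, c("q", "gev", "W", "kl"))
  # gev column is monotone, so the smallest qualifying q is unique
  expect_true(all(diff(sel$criteria$gev) >= -1e-12))
  expect_true(all(sel$criteria$gev[sel$criteria$q > sel$q_star] >= 0.9))
})

test_that("noisy map-count recovery succeeds in most replicates", {
  set.seed(8)
  hits <- 0
  for (r in 1:15) {
    maps <- apply(matrix(rnorm(16 * 3), 16), 2,
                  function(m) (m - mean(m)) / gfp(m - mean(m)))
    lab <- rep(1:3, each = 8)
    V <- maps[, lab] * rep(runif(24, 0.8, 1.2), each = 16)
    nz <- matrix(rnorm(length(V), 0,
                       sqrt(mean(gfp(V)^2) / 10)), nrow(V))   # 10 dB
    Vn <- V + sweep(nz, 2, colMeans(nz))
    sel <- select_n_maps(aahc_cluster(Vn, 1:6), Vn, 0.90)
    hits <- hits + (sel$q_star == 3)
  }
  expect_gte(hits / 15, 0.9)
})

test_that("template fitting is winner-take-all with exact duration
           conservation and deterministic tie-breaks", {
  set.seed(9)
  n_ch <- 16; n_t <- 179; sfreq <- 512
  A <- rand_topo(n_ch); B <- rand_topo(n_ch)
  B <- B - A * sum(A * B) / sum(A^2)
  maps <- cbind(map1 = A / gfp(A), map2 = B / gfp(B))
  # subjects follow map A in congruent cells, map B otherwise
  ev <- make_evoked(4, n_ch, n_t, gen = function(s, cond) {
    base <- if (grepl("^congruent", cond)) A else B
    outer(base, rep(1, n_t)) + matrix(rnorm(n_ch * n_t, 0, 1e-4), n_ch)
  })
  fr <- fit_templates(ev, maps, window = c(20, 55))
  win_len <- sum(time_axis(ev) * 1000 >= 20 & time_axis(ev) * 1000 < 55) /
    sfreq * 1000
  sums <- fr |>
    dplyr::group_by(subject, condition) |>
    dplyr::summarise(tot = sum(duration_ms), .groups = "drop")
  expect_true(all(sums$tot == win_len))       # exact conservation
  a_cong <- fr$duration_ms[fr$map == "map1" & fr$congruency == "congruent"]
  a_incong <- fr$duration_ms[fr$map == "map1" &
                               fr$congruency == "incongruent"]
  expect_true(all(a_cong == win_len))
  expect_true(all(a_incong == 0))
  expect_true(all(is.na(fr$gfp_uv[fr$map == "map2" &
                                    fr$congruency == "congruent"])))
  # exact ties go to the lowest map index
  tie_ev <- make_evoked(1, n_ch, 10, t0 = 0, gen = function(s, cond)
    outer(A + B, rep(1, 10)))
  tie <- fit_templates(tie_ev, cbind(m1 = A + B, m2 = A + B), c(0, 10))
  expect_true(all(tie$duration_ms[tie$map == "m1"] > 0))
  expect_true(all(tie$duration_ms[tie$map == "m2"] == 0))
  expect_error(fit_templates(ev, maps, c(-500, 900)), "window")
})

test_that("window selection intersects stable topography, consistency and
           the GFP peak", {
  n_t <- 40
  times <- seq(0, by = 2, length.out = n_t)
  labs <- matrix(rep(c(rep(1L, 15), rep(2L, 15), rep(3L, 10)), 4), n_t, 4)
  gfp_curve <- c(seq(0.1, 2, length.out = 20), seq(2, 0.1, length.out = 20))
  mk_tct <- function(p_vec) {
    d <- do.call(rbind, lapply(design_cells()$condition, function(cond)
      tibble::tibble(condition = cond, time_ms = times, gfp_obs = gfp_curve,
                     p = p_vec)))
    class(d) <- unique(c("tct_result", class(d)))
    d
  }
  # significant everywhere: the run containing the GFP peak comes back whole
  w <- select_window(labs, mk_tct(rep(0.001, n_t)), times)
  expect_equal(nrow(w), 1)
  expect_equal(w$start_ms, 30)                 # second label run
  expect_equal(w$end_ms, 60)
  # consistency only over part of the run: the window is the intersection
  p_part <- rep(1, n_t); p_part[13:25] <- 0.001
  w2 <- select_window(labs, mk_tct(p_part), times)
  expect_equal(w2$start_ms, 30)
  expect_equal(w2$end_ms, 50)                  # cut at the consistency edge
  # nothing significant anywhere -> empty with a warning
  expect_warning(w3 <- select_window(labs, mk_tct(rep(0.9, n_t)), times),
                 "consistent")
  expect_equal(nrow(w3), 0)
})

test_that("a planted consistent window is recovered with high coverage", {
  set.seed(10)
  n_sub <- 8; n_ch <- 16; n_t <- 80; sfreq <- 512
  times <- (seq_len(n_t) - 1) / sfreq * 1000
  planted <- times >= 40 & times < 100          # the planted stable period
  topo <- rand_topo(n_ch)
  bump <- exp(-0.5 * ((times - 70) / 18)^2)
  coverage <- numeric(30)
  for (r in 1:30) {
    ev <- make_evoked(n_sub, n_ch, n_t, t0 = 0, gen = function(s, cond) {
      sig <- outer(topo, bump * planted)
      sig + matrix(rnorm(n_ch * n_t, 0, 0.12), n_ch)
    })
    post <- seq_len(n_t)
    grand <- lapply(ev$conditions, function(cond)
      Reduce(`+`, lapply(ev$subjects,
                         function(s) ev$evoked[[s]][[cond]])) / n_sub)
    V <- do.call(cbind, grand)
    sel <- select_n_maps(aahc_cluster(V, 1:5), V, 0.9)
    L <- matrix(sel$templates$labels, n_t, 4)
    tct <- tct_test(ev, n_permutations = 99, seed = r)
    w <- suppressWarnings(select_window(L, tct, times))
    if (nrow(w) == 0) { coverage[r] <- 0; next }
    lo <- max(w$start_ms[1], 40); hi <- min(w$end_ms[1], 100)
    coverage[r] <- max(0, hi - lo) / 60
  }
  expect_gte(mean(coverage), 0.8)
})
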