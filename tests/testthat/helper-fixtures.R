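# Shared fixtures and independent oracles. Everything is generated in code;
# oracles are deliberately naive re-implementations, kept separate from the
# package's own algorithms.

rand_topo <- function(n_ch) {
  u <- rnorm(n_ch)
  u - mean(u)
}

# small average-referenced topography series with controllable structure
rand_topo_series <- function(n_ch, n_t) {
  V <- matrix(rnorm(n_ch * n_t), n_ch, n_t)
  sweep(V, 2, colMeans(V))
}

# Build an evoked_dataset from a function (subject, condition) -> channels x
# samples matrix; matrices are average-referenced on the way in.
make_evoked <- function(n_sub, n_ch, n_t, sfreq = 512, t0 = -0.05,
                        montage = NULL, gen) {
  montage <- montage %||% montage_sphere(n_ch)
  subjects <- sprintf("s%02d", seq_len(n_sub))
  cells <- design_cells()$condition
  evoked <- list()
  for (s in subjects) {
    for (cond in cells) {
      m <- gen(s, cond)
      evoked[[s]][[cond]] <- sweep(m, 2, colMeans(m))
    }
  }
  evoked_dataset(evoked, NULL, sfreq, t0, montage)
}

`%||%` <- rlang::`%||%`

# --- independent oracles ---------------------------------------------------

# flood-fill connected components by explicit BFS over an adjacency list
bfs_components <- function(members, neighbors) {
  unseen <- rep(TRUE, length(members))
  names(unseen) <- members
  comps <- list()
  for (start in members) {
    if (!unseen[as.character(start)]) next
    queue <- start
    unseen[as.character(start)] <- FALSE
    comp <- c()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (nb in intersect(neighbors[[v]], members)) {
        if (unseen[as.character(nb)]) {
          unseen[as.character(nb)] <- FALSE
          queue <- c(queue, nb)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# classical repeated-measures 2x2 F from base aov with the Error() strata
aov_rm_f <- function(tbl, outcome) {
  tbl$y <- tbl[[outcome]]
  tbl$subject <- factor(tbl$subject)
  tbl$congruency <- factor(tbl$congruency)
  tbl$synchrony <- factor(tbl$synchrony)
  fit <- summary(aov(y ~ congruency * synchrony +
                       Error(subject / (congruency * synchrony)),
                     data = tbl))
  c(congruency = fit[["Error: subject:congruency"]][[1]]["congruency", "F value"],
    synchrony = fit[["Error: subject:synchrony"]][[1]]["synchrony", "F value"],
    interaction = fit[["Error: subject:congruency:synchrony"]][[1]][
      "congruency:synchrony", "F value"])
}

# naive step-by-step AAHC: same definitions as the package (min-contribution
# atomization, signed-correlation reassignment, GFP-weighted templates) but
# written as plain loops, recomputing everything from scratch at each step
aahc_naive <- function(V, q_record) {
  n_t <- ncol(V)
  g <- apply(V, 2, gfp)
  corr <- function(a, b) cor(a, b)
  template_of <- function(members) {
    cV <- sweep(V[, members, drop = FALSE], 2,
                colMeans(V[, members, drop = FALSE]))
    m <- as.numeric(cV %*% g[members])
    if (sqrt(sum(m^2)) == 0) m <- cV[, 1]
    m
  }
  contribution <- function(members, tmpl) {
    sum(vapply(members, function(t) (g[t] * corr(V[, t], tmpl))^2, 0))
  }
  clusters <- as.list(seq_len(n_t))
  out <- list()
  repeat {
    k <- length(clusters)
    if (k %in% q_record) {
      labels <- integer(n_t)
      for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
      # renumber by first occurrence as the package does
      first <- vapply(clusters, min, 0L)
      ord <- order(first)
      relab <- match(labels, ord)
      out[[paste0("q", k)]] <- relab
    }
    if (k == 1) break
    tmpls <- lapply(clusters, template_of)
    contribs <- mapply(contribution, clusters, tmpls)
    worst <- which.min(contribs)
    orphans <- clusters[[worst]]
    clusters <- clusters[-worst]
    tmpls <- tmpls[-worst]
    # all orphans are reassigned against the templates as they stand after
    # the atomization; templates are recomputed only afterwards
    for (t in orphans) {
      rs <- vapply(tmpls, function(m) corr(V[, t], m), 0)
      best <- which.max(rs)
      clusters[[best]] <- sort(c(clusters[[best]], t))
    }
  }
  out
}

# independent reversal-segmentation oracle for trajectory features
trajectory_oracle <- function(traj) {
  P <- as.matrix(traj[, setdiff(names(traj), "t_s")])
  t <- traj$t_s
  axis <- stats::prcomp(P)$rotation[, 1]
  u <- as.numeric(P %*% axis)
  dirs <- c()
  idx <- c()
  for (i in 2:length(u)) {
    if (u[i] != u[i - 1]) {
      dirs <- c(dirs, sign(u[i] - u[i - 1]))
      idx <- c(idx, i - 1L)
    }
  }
  turns <- c()
  for (j in 2:length(dirs)) {
    # the reversal sample is where the OLD direction's last step ended
    if (dirs[j] != dirs[j - 1]) turns <- c(turns, idx[j - 1] + 1L)
  }
  norms <- c()
  if (length(turns) >= 2) {
    for (j in 2:length(turns)) {
      norms <- c(norms, sqrt(sum((P[turns[j], ] - P[turns[j - 1], ])^2)))
    }
  } else {
    norms <- sqrt(sum((P[nrow(P), ] - P[1, ])^2))
  }
  path <- sum(sqrt(rowSums(diff(P)^2)))
  list(norm = mean(norms), velocity = path / (t[length(t)] - t[1]))
}

# small shared source space + lead field for inverse tests (computed once)
test_space <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_source_space(36, 10, 26)
    val
  }
})
test_lead <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- leadfield_single_sphere(test_space(),
                                                      montage_sphere(64), 90)
    val
  }
})

# named per-cell constant vectors for behavioral configs
rep_cells_sd <- function(x) setNames(rep(x, 4), design_cells()$condition)
rep_cells_flat <- rep_cells_sd
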