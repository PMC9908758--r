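#' Build a regular-grid source space inside a spherical volume
#'
#' Nodes are placed on a regular grid (step `spacing` mm, centered on the
#' origin) and kept when they fall within `radius` mm of the center. The
#' neighbor graph connects nodes one grid step apart under the chosen
#' connectivity (6 = faces, 18 = faces + edges, 26 = full 3x3x3 shell).
#'
#' @param radius sphere radius in mm.
#' @param spacing grid step in mm (default 2, a 2x2x2 mm grid).
#' @param connectivity one of 6, 18, 26.
#' @return object of class `source_space`: `nodes` (n x 3 mm), `spacing`,
#'   `connectivity`, `neighbors` (adjacency list), `n_nodes`.
#' @export
build_source_space <- function(radius, spacing = 2, connectivity = 26) {
  stopifnot(is_number(radius), radius > 0, is_number(spacing), spacing > 0)
  if (!connectivity %in% c(6, 18, 26)) abort("connectivity must be 6, 18 or 26")
  k <- floor(radius / spacing)
  ax <- seq(-k, k) * spacing
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  g <- g[rowSums(g^2) <= radius^2, , drop = FALSE]
  n <- nrow(g)
  if (n < 1) abort("no grid node falls inside the volume")
  ig <- round(g / spacing)
  key <- paste(ig[, 1], ig[, 2], ig[, 3])
  lookup <- stats::setNames(seq_len(n), key)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  off <- switch(as.character(connectivity),
    "6" = off[rowSums(abs(off)) == 1, , drop = FALSE],
    "18" = off[rowSums(off^2) <= 2, , drop = FALSE],
    "26" = off)
  neighbors <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- sweep(off, 2, as.numeric(ig[i, ]), "+")
    hits <- lookup[paste(cand[, 1], cand[, 2], cand[, 3])]
    neighbors[[i]] <- unname(hits[!is.na(hits)])
  }
  if (any(lengths(neighbors) == 0)) {
    abort("source space has isolated node(s); decrease spacing or enlarge the volume")
  }
  structure(list(nodes = unname(g), spacing = spacing,
                 connectivity = connectivity, neighbors = neighbors,
                 n_nodes = n),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat_line(sprintf(
    "<source_space> %d nodes, %g mm grid, %d-connectivity",
    x$n_nodes, x$spacing, x$connectivity))
  invisible(x)
}

# Legendre P_n(x) and derivative P'_n(x) for n = 1..N, x a vector.
# Recurrences: (n+1) P_{n+1} = (2n+1) x P_n - n P_{n-1};
# (x^2 - 1) P'_n = n (x P_n - P_{n-1}).
legendre_terms <- function(x, N) {
  P <- matrix(0, length(x), N + 1L)
  P[, 1] <- 1
  P[, 2] <- x
  if (N >= 2) {
    for (n in 1:(N - 1)) {
      P[, n + 2] <- ((2 * n + 1) * x * P[, n + 1] - n * P[, n]) / (n + 1)
    }
  }
  dP <- matrix(0, length(x), N + 1L)
  dP[, 2] <- 1
  denom <- x^2 - 1
  sing <- abs(denom) < 1e-12
  for (n in 2:N) {
    dP[, n + 1] <- ifelse(sing,
                          # at |x| = 1: P'_n(1) = n(n+1)/2, with sign (x)^(n+1)
                          sign(x)^(n + 1) * n * (n + 1) / 2,
                          n * (x * P[, n + 1] - P[, n]) / denom)
  }
  list(P = P, dP = dP)
}

#' Analytic lead field for dipoles in a homogeneous conducting sphere
#'
#' Quasi-static surface potential of a current dipole inside a single
#' homogeneous sphere, evaluated by the classical Legendre-series
#' expansion. With electrode direction `e`, dipole position `b * bhat`
#' (eccentricity `f = b/R`) and unit moment `u`,
#' `V = K * sum_n ((2n+1)/n) f^(n-1) [ n (u.bhat) P_n(c) +
#'  (u.e - (u.bhat) c) P_n'(c) ]` with `c = bhat.e`, `K = 1/(4 pi sigma R^2)`.
#' The series is truncated when `f^(n-1)` falls below 1e-12. Columns are
#' ordered node-major (`node1_x, node1_y, node1_z, node2_x, ...`), scaled so
#' that unit moments are 1 nAm and potentials come out in uV, and are
#' average-referenced (each column sums to zero).
#'
#' @param space a [build_source_space()] result (node coordinates in mm).
#' @param montage an [electrode_montage()]; unit-sphere positions are scaled
#'   to `head_radius_mm`.
#' @param head_radius_mm scalp sphere radius (mm); must exceed every node
#'   radius.
#' @param sigma conductivity in S/m (default 0.33).
#' @return object of class `lead_field`: `L` (n_channels x 3*n_nodes, uV per
#'   nAm), `montage`, `head_radius_mm`, `sigma`, `model = "single_sphere_analytic"`.
#' @export
leadfield_single_sphere <- function(space, montage, head_radius_mm = 90,
                                    sigma = 0.33) {
  pos <- montage_positions(montage)
  pos <- pos / sqrt(rowSums(pos^2))          # force unit sphere
  R <- head_radius_mm
  nodes <- space$nodes
  rad <- sqrt(rowSums(nodes^2))
  if (any(rad >= R)) {
    abort("every source node must lie strictly inside the electrode sphere")
  }
  n_ch <- nrow(pos)
  n_nd <- nrow(nodes)
  # SI prefactor, then nAm -> uV: 1e-9 * 1e6
  K <- 1e-3 / (4 * pi * sigma * (R / 1000)^2)
  L <- matrix(0, n_ch, 3L * n_nd)
  I3 <- diag(3)
  for (i in seq_len(n_nd)) {
    b <- rad[i]
    f <- b / R
    if (b < 1e-9) {
      # central dipole: exact closed form V = 3 K (u . e)
      for (cc in 1:3) L[, 3L * (i - 1L) + cc] <- 3 * K * pos[, cc]
      next
    }
    bhat <- nodes[i, ] / b
    x <- as.numeric(pos %*% bhat)            # cos(gamma) per electrode
    N <- if (f < 0.05) 5L else min(500L, max(30L, ceiling(1 - 12 / log10(f))))
    lt <- legendre_terms(x, N)
    ns <- seq_len(N)
    cn <- (2 * ns + 1) / ns * f^(ns - 1)
    S1 <- as.numeric(lt$P[, ns + 1L, drop = FALSE] %*% (cn * ns))
    S2 <- as.numeric(lt$dP[, ns + 1L, drop = FALSE] %*% cn)
    for (cc in 1:3) {
      u <- I3[, cc]
      ub <- sum(u * bhat)
      ue <- pos[, cc]
      L[, 3L * (i - 1L) + cc] <- K * (ub * (S1 - x * S2) + ue * S2)
    }
  }
  L <- sweep(L, 2, colMeans(L), "-")         # average reference
  structure(list(L = L, montage = montage, head_radius_mm = head_radius_mm,
                 sigma = sigma, model = "single_sphere_analytic",
                 n_nodes = n_nd),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat_line(sprintf("<lead_field> %d channels x %d nodes (%s)",
                   nrow(x$L), x$n_nodes, x$model))
  invisible(x)
}

#' Wrap a user-supplied lead-field matrix
#'
#' @param L n_channels x (3 * n_nodes) matrix (uV per nAm); rows are
#'   average-referenced on input.
#' @param montage matching [electrode_montage()].
#' @return a `lead_field` object with `model = "user_supplied"`.
#' @export
lead_field_matrix <- function(L, montage) {
  L <- as.matrix(L)
  if (!all(is.finite(L))) abort("lead field must be finite")
  if (nrow(L) != nrow(montage)) abort("lead field rows must match the montage")
  if (ncol(L) %% 3 != 0) abort("lead field needs 3 columns per node")
  L <- sweep(L, 2, colMeans(L), "-")
  structure(list(L = L, montage = montage, head_radius_mm = NA_real_,
                 sigma = NA_real_, model = "user_supplied",
                 n_nodes = ncol(L) / 3L),
            class = "lead_field")
}
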