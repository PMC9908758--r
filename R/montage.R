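#' Electrode montage
#'
#' An electrode montage is a tibble with one row per channel: the channel
#' `label` and head-centered cartesian coordinates `x`, `y`, `z` on (or near)
#' a unit sphere. Orientation convention: +x right, +y anterior (nasion),
#' +z vertex.
#'
#' @param labels character vector of unique channel names.
#' @param positions numeric matrix, one row per channel, columns x, y, z.
#' @return a tibble of class `eeg_montage` with columns label, x, y, z.
#' @export
electrode_montage <- function(labels, positions) {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  if (anyDuplicated(labels)) {
    abort(paste0("duplicate channel labels: ",
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  if (nrow(positions) != length(labels) || ncol(positions) != 3) {
    abort("`positions` must be a length(labels) x 3 matrix")
  }
  if (!all(is.finite(positions))) abort("electrode positions must be finite")
  if (length(labels) < 2) abort("a montage needs at least 2 channels")
  out <- tibble::tibble(
    label = unname(labels),
    x = unname(positions[, 1]), y = unname(positions[, 2]),
    z = unname(positions[, 3])
  )
  class(out) <- c("eeg_montage", class(out))
  out
}

montage_positions <- function(montage) {
  m <- as.matrix(montage[, c("x", "y", "z")])
  rownames(m) <- montage$label
  m
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat_line(sprintf("<eeg_montage> %d channels", nrow(x)))
  NextMethod()
}

# Spherical linear interpolation between two unit vectors.
slerp <- function(p, q, f) {
  p <- p / sqrt(sum(p^2)); q <- q / sqrt(sum(q^2))
  om <- acos(max(-1, min(1, sum(p * q))))
  if (om < 1e-12) return(p)
  (sin((1 - f) * om) * p + sin(f * om) * q) / sin(om)
}

sph_point <- function(polar_deg, az_deg) {
  # polar: angle from vertex (Cz); azimuth: 0 = front midline, positive to
  # the LEFT going clockwise seen from above (front -> left -> back).
  th <- polar_deg * pi / 180
  ph <- az_deg * pi / 180
  c(x = -sin(th) * sin(ph), y = sin(th) * cos(ph), z = cos(th))
}

#' Standard 64-channel 10-10 montage on a unit sphere
#'
#' Generates the 64 extended 10-20 ("10-10") electrode positions used by
#' common 64-channel caps (including the midline sites Fz, Cz, Pz, Oz) by the
#' geodesic construction of the international system: midline sites at 10%
#' steps along the nasion-inion arc, the lateral circumferential circle at
#' 18-degree azimuthal steps, and intermediate rows by spherical
#' interpolation between the midline and circumferential sites.
#'
#' @return an [electrode_montage()] with 64 channels.
#' @export
#' @examples
#' m <- montage_1010_64()
#' subset(m, label %in% c("Fz", "Cz", "Pz", "Oz"))
montage_1010_64 <- function() {
  pts <- list()
  # Midline: Fpz at 10% of the nasion-inion arc ... Oz at 90%, Iz at inion.
  mid <- c(Fpz = -72, AFz = -54, Fz = -36, FCz = -18, Cz = 0,
           CPz = 18, Pz = 36, POz = 54, Oz = 72, Iz = 90)
  for (lab in names(mid)) {
    a <- mid[[lab]]
    pts[[lab]] <- sph_point(abs(a), if (a < 0) 0 else 180)
  }
  # Circumferential circle (polar 72 deg), azimuth in 18 deg steps from front.
  circ <- c(Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90,
            TP7 = 108, P7 = 126, PO7 = 144, O1 = 162)
  for (lab in names(circ)) {
    pts[[lab]] <- sph_point(72, circ[[lab]])                  # left
    rlab <- sub("7$", "8", sub("1$", "2", lab))
    pts[[rlab]] <- sph_point(72, -circ[[lab]])                # mirrored right
  }
  # Intermediate rows: fractional arcs from the midline site to the
  # circumferential site of the same row (1/4, 2/4, 3/4 for x1, x3, x5).
  rows <- list(
    AF = list(mid = "AFz", edge = "AF7", at = c(AF3 = 0.5)),
    F  = list(mid = "Fz",  edge = "F7",  at = c(F1 = 0.25, F3 = 0.5, F5 = 0.75)),
    FC = list(mid = "FCz", edge = "FT7", at = c(FC1 = 0.25, FC3 = 0.5, FC5 = 0.75)),
    C  = list(mid = "Cz",  edge = "T7",  at = c(C1 = 0.25, C3 = 0.5, C5 = 0.75)),
    CP = list(mid = "CPz", edge = "TP7", at = c(CP1 = 0.25, CP3 = 0.5, CP5 = 0.75)),
    P  = list(mid = "Pz",  edge = "P7",  at = c(P1 = 0.25, P3 = 0.5, P5 = 0.75)),
    PO = list(mid = "POz", edge = "PO7", at = c(PO3 = 0.5))
  )
  flip_lr <- function(p) c(-p[1], p[2], p[3])
  right_label <- function(lab) {
    n <- as.integer(sub("^[A-Za-z]+", "", lab))
    paste0(sub("[0-9]+$", "", lab), n + 1L)
  }
  for (row in rows) {
    for (lab in names(row$at)) {
      p <- slerp(pts[[row$mid]], pts[[row$edge]], row$at[[lab]])
      pts[[lab]] <- p
      pts[[right_label(lab)]] <- flip_lr(p)
    }
  }
  # Inferior temporal-posterior sites on the equator at the P meridian.
  pts[["P9"]] <- sph_point(90, 126)
  pts[["P10"]] <- sph_point(90, -126)
  order64 <- c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz", "Fpz",
    "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8", "FC6",
    "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6", "CP4",
    "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2"
  )
  electrode_montage(order64, do.call(rbind, pts[order64]))
}

#' Small montage for quick examples and simulations
#'
#' An approximately uniform spherical arrangement of `n` electrodes on the
#' upper hemisphere (Fibonacci lattice), labelled E1..En. Useful for fast
#' tests and reduced-size simulations; not a standard clinical layout.
#'
#' @param n number of channels (>= 2).
#' @return an [electrode_montage()].
#' @export
montage_sphere <- function(n = 32) {
  stopifnot(is_count(n), n >= 2)
  i <- seq_len(n) - 0.5
  z <- 1 - i / n            # upper hemisphere: z in (0, 1)
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  electrode_montage(paste0("E", seq_len(n)),
                    cbind(r * cos(phi), r * sin(phi), z))
}
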