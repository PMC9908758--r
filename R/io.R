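#' Write an epoched collection or evoked dataset to the canonical layout
#'
#' The canonical on-disk dataset is a directory with a JSON header
#' (`dataset.json`: montage, sampling metadata, design, provenance) and one
#' little-endian float64 binary per subject x condition array, plus a
#' `manifest.json` listing every file with its SHA-256 checksum. The format
#' round-trips bit-identically, which is what the package's reproducibility
#' tests rely on.
#'
#' @param data a list of [epoched_eeg()] objects or an [evoked_dataset()].
#' @param path output directory (created if needed).
#' @param provenance optional named list stored verbatim in the header
#'   (e.g., seeds, config hash).
#' @return invisibly, the manifest tibble (file, bytes, sha256).
#' @export
write_dataset <- function(data, path, provenance = list()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  arr_dir <- file.path(path, "arrays")
  dir.create(arr_dir, showWarnings = FALSE)
  if (inherits(data, "evoked_dataset")) {
    # re-validate before writing: enforces design completeness
    data <- evoked_dataset(data$evoked, data$n_epochs_used, data$sfreq,
                           data$t0, data$montage)
    kind <- "evoked"
    montage <- data$montage
    records <- list()
    for (s in data$subjects) {
      for (cond in data$conditions) {
        m <- data$evoked[[s]][[cond]]
        fn <- sprintf("%s_%s.bin", s, cond)
        write_f64(file.path(arr_dir, fn), as.numeric(m))
        records[[length(records) + 1L]] <- list(
          subject = s, condition = cond, file = file.path("arrays", fn),
          dims = dim(m))
      }
    }
    header <- list(
      format = "evtopo-canonical", version = 1L, kind = kind,
      sfreq = data$sfreq, t0 = data$t0,
      montage = list(label = montage$label, x = montage$x, y = montage$y,
                     z = montage$z),
      records = records,
      n_epochs_used = if (!is.null(data$n_epochs_used))
        as.list(data$n_epochs_used) else NULL,
      provenance = provenance
    )
  } else {
    if (inherits(data, "epoched_eeg")) data <- list(data)
    stopifnot(all(vapply(data, inherits, logical(1), "epoched_eeg")))
    montage <- data[[1]]$montage
    records <- list()
    for (ep in data) {
      if (!identical(ep$montage$label, montage$label)) {
        abort("all epoched_eeg objects in a dataset must share one montage")
      }
      fn <- sprintf("%s_%s.bin", ep$subject, ep$condition)
      write_f64(file.path(arr_dir, fn), as.numeric(ep$data))
      records[[length(records) + 1L]] <- list(
        subject = ep$subject, condition = ep$condition,
        file = file.path("arrays", fn), dims = dim(ep$data),
        sfreq = ep$sfreq, t0 = ep$t0)
    }
    header <- list(
      format = "evtopo-canonical", version = 1L, kind = "epoched",
      sfreq = data[[1]]$sfreq, t0 = data[[1]]$t0,
      montage = list(label = montage$label, x = montage$x, y = montage$y,
                     z = montage$z),
      records = records, provenance = provenance
    )
  }
  jsonlite::write_json(header, file.path(path, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- c("dataset.json",
             file.path("arrays", vapply(records, function(r) basename(r$file),
                                        character(1))))
  manifest <- tibble::tibble(
    file = files,
    bytes = vapply(file.path(path, files),
                   function(f) file.size(f), numeric(1), USE.NAMES = FALSE),
    sha256 = vapply(file.path(path, files),
                    function(f) digest::digest(file = f, algo = "sha256"),
                    character(1), USE.NAMES = FALSE)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

write_f64 <- function(fn, x) {
  con <- file(fn, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8, endian = "little")
}

read_f64 <- function(fn, n) {
  con <- file(fn, "rb")
  on.exit(close(con))
  readBin(con, "numeric", n = n, size = 8, endian = "little")
}

#' Read an EEG dataset
#'
#' Reads the canonical directory layout written by [write_dataset()]
#' bit-identically, or imports external formats (BrainVision, EDF) as
#' conveniences. EEGLAB `.set` files (a MATLAB container) are not supported.
#'
#' @param path dataset directory (canonical) or file (importers).
#' @param format one of `"canonical"`, `"brainvision"`, `"edf"`,
#'   `"eeglab_set"`.
#' @param montage montage for importers; for canonical data the montage is
#'   stored in the header. Channels present in the file but absent from the
#'   montage cause a validation error naming them.
#' @param ... passed to the format-specific importer (`epoch_window`,
#'   `marker_regex`, `event_samples`, ...).
#' @return a list of [epoched_eeg()] (canonical/importers) or an
#'   [evoked_dataset()] if the canonical directory stores evoked data.
#' @export
read_dataset <- function(path, format = c("canonical", "brainvision", "edf",
                                          "eeglab_set"),
                         montage = NULL, ...) {
  format <- match.arg(format)
  switch(format,
    canonical = read_canonical(path),
    brainvision = read_brainvision(path, montage = montage, ...),
    edf = read_edf(path, montage = montage, ...),
    eeglab_set = abort(paste0(
      "unsupported format 'eeglab_set': EEGLAB .set files are MATLAB v5 ",
      "containers; export to BrainVision or EDF, or convert to the ",
      "canonical layout"))
  )
}

read_canonical <- function(path) {
  hdr_file <- file.path(path, "dataset.json")
  if (!file.exists(hdr_file)) abort(sprintf("no canonical dataset at %s", path))
  hdr <- jsonlite::read_json(hdr_file, simplifyVector = TRUE)
  montage <- electrode_montage(hdr$montage$label,
                               cbind(hdr$montage$x, hdr$montage$y, hdr$montage$z))
  recs <- hdr$records
  if (identical(hdr$kind, "evoked")) {
    evoked <- list()
    for (i in seq_len(nrow(recs))) {
      dims <- unlist(recs$dims[i])
      m <- matrix(read_f64(file.path(path, recs$file[i]), prod(dims)),
                  dims[1], dims[2])
      evoked[[recs$subject[i]]][[recs$condition[i]]] <- m
    }
    n_used <- if (!is.null(hdr$n_epochs_used))
      tibble::as_tibble(hdr$n_epochs_used) else NULL
    evoked_dataset(evoked, n_used, hdr$sfreq, hdr$t0, montage)
  } else {
    lapply(seq_len(nrow(recs)), function(i) {
      dims <- unlist(recs$dims[i])
      a <- array(read_f64(file.path(path, recs$file[i]), prod(dims)), dims)
      epoched_eeg(a, hdr$sfreq, hdr$t0, recs$subject[i], recs$condition[i],
                  montage)
    })
  }
}

check_channels_in_montage <- function(labels, montage) {
  missing <- setdiff(labels, montage$label)
  if (length(missing)) {
    abort(sprintf("channel(s) not in montage: %s",
                  paste(missing, collapse = ", ")))
  }
  match(labels, montage$label)
}

# Minimal BrainVision importer: INI-style .vhdr + multiplexed binary .eeg
# (+ .vmrk stimulus markers used as epoch triggers). Values are scaled to uV
# by each channel's resolution field.
read_brainvision <- function(path, montage, epoch_window = c(-0.05, 0.3),
                             marker_regex = "^Stimulus", subject = NULL,
                             condition = "imported") {
  if (is.null(montage)) abort("a montage is required to import BrainVision data")
  lines <- readLines(path, warn = FALSE)
  kv <- function(key) {
    ln <- grep(sprintf("^%s=", key), lines, value = TRUE)[1]
    if (is.na(ln)) abort(sprintf("missing %s in %s", key, path)) else
      sub(sprintf("^%s=", key), "", ln)
  }
  if (toupper(kv("DataFormat")) != "BINARY" ||
      toupper(kv("DataOrientation")) != "MULTIPLEXED") {
    abort("only BINARY MULTIPLEXED BrainVision data are supported")
  }
  bin_fmt <- toupper(kv("BinaryFormat"))
  n_ch <- as.integer(kv("NumberOfChannels"))
  sfreq <- 1e6 / as.numeric(kv("SamplingInterval"))
  ch <- grep("^Ch[0-9]+=", lines, value = TRUE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch), ",")
  labels <- vapply(parts, `[`, character(1), 1)
  resol <- vapply(parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3])); if (is.na(r)) 1 else r
  }, numeric(1))
  idx <- check_channels_in_montage(labels, montage)
  if (length(labels) != nrow(montage)) {
    abort(sprintf("file has %d channels, montage has %d",
                  length(labels), nrow(montage)))
  }
  eeg_file <- file.path(dirname(path), kv("DataFile"))
  raw_n <- file.size(eeg_file)
  con <- file(eeg_file, "rb")
  on.exit(close(con))
  sig <- switch(bin_fmt,
    IEEE_FLOAT_32 = readBin(con, "numeric", raw_n / 4, size = 4,
                            endian = "little"),
    INT_16 = readBin(con, "integer", raw_n / 2, size = 2, signed = TRUE,
                     endian = "little"),
    abort(sprintf("unsupported BinaryFormat %s", bin_fmt)))
  sig <- matrix(sig, nrow = n_ch)              # channels x samples
  sig <- sig * resol                           # to uV
  vmrk <- file.path(dirname(path), kv("MarkerFile"))
  mk <- grep("^Mk[0-9]+=", readLines(vmrk, warn = FALSE), value = TRUE)
  mparts <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
  types <- vapply(mparts, `[`, character(1), 1)
  onsets <- as.integer(vapply(mparts, `[`, character(1), 3))
  onsets <- onsets[grepl(marker_regex, types)]
  segment_epochs(sig, onsets, sfreq, epoch_window,
                 montage[idx, , drop = FALSE],
                 subject %||% sub("\\.vhdr$", "", basename(path)), condition)
}

segment_epochs <- function(sig, onsets, sfreq, epoch_window, montage,
                           subject, condition) {
  pre <- round(epoch_window[1] * sfreq)
  post <- round(epoch_window[2] * sfreq)
  len <- post - pre
  keep <- onsets + pre >= 0 & onsets + post <= ncol(sig)
  onsets <- onsets[keep]
  if (!length(onsets)) abort("no usable epoch onsets within the recording")
  a <- array(0, c(length(onsets), nrow(sig), len))
  for (i in seq_along(onsets)) {
    a[i, , ] <- sig[, (onsets[i] + pre + 1L):(onsets[i] + post)]
  }
  list(epoched_eeg(a, sfreq, epoch_window[1], subject, condition, montage))
}

# Minimal EDF importer (continuous recording; the caller supplies event
# sample indices to epoch around). 16-bit integers mapped to physical units
# via the per-signal calibration; physical dimension is assumed uV.
read_edf <- function(path, montage, event_samples, epoch_window = c(-0.05, 0.3),
                     subject = NULL, condition = "imported") {
  if (is.null(montage)) abort("a montage is required to import EDF data")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(8); rd(80); rd(80); rd(8); rd(8)          # version, patient, rec, date, time
  rd(8)                                        # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  nsamp <- as.integer(fld(8)); fld(32)
  if (length(unique(nsamp)) != 1) abort("EDF signals must share one rate")
  sfreq <- nsamp[1] / dur
  idx <- check_channels_in_montage(labels, montage)
  gain <- (pmax - pmin) / (dmax - dmin)
  sig <- matrix(0, ns, n_rec * nsamp[1])
  for (r in seq_len(n_rec)) {
    blk <- readBin(con, "integer", ns * nsamp[1], size = 2, signed = TRUE,
                   endian = "little")
    blk <- matrix(blk, nrow = nsamp[1])        # samples x signals
    cols <- ((r - 1L) * nsamp[1] + 1L):(r * nsamp[1])
    sig[, cols] <- t(blk * rep(gain, each = nsamp[1]) +
                       rep(pmin - gain * dmin, each = nsamp[1]))
  }
  segment_epochs(sig, as.integer(event_samples), sfreq, epoch_window,
                 montage[idx, , drop = FALSE],
                 subject %||% sub("\\.edf$", "", basename(path)), condition)
}
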