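#' Construct a calibrated AFM height frame
#'
#' A `scan_frame` bundles one height image with its physical calibration and
#' acquisition time. Heights are in nanometres; `pixel_size` is the isotropic
#' sampling interval in nm/px. The physical coordinate convention used by the
#' whole pipeline is fixed here: pixel `(i, j)` (row `i` from the top, column
#' `j` from the left, 1-based) maps to
#' `x = (j - 0.5) * pixel_size`, `y = (nrow - i + 0.5) * pixel_size`,
#' i.e. x grows rightward and y grows upward from the bottom-left corner, and
#' every centroid and distance downstream is in nm under this convention.
#'
#' @param heights numeric matrix of heights in nm (rows = scan lines).
#' @param pixel_size pixel size in nm/px, strictly positive.
#' @param timestamp acquisition time in seconds since sample injection.
#' @param frame_index integer frame number within its series (0-based).
#' @return An object of class `scan_frame` with fields `heights`,
#'   `pixel_size`, `timestamp`, `frame_index` and `field_size` (µm per side,
#'   derived from the column count).
#' @examples
#' f <- scan_frame(matrix(0, 200, 200), pixel_size = 5)
#' f$field_size  # 1 µm
#' @export
scan_frame <- function(heights, pixel_size, timestamp = 0, frame_index = 0L) {
  if (!is.matrix(heights) || !is.numeric(heights))
    stop("heights must be a numeric matrix")
  if (!all(is.finite(heights)))
    stop("heights must be finite-valued")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (nm/px)")
  structure(
    list(
      heights = heights,
      pixel_size = as.numeric(pixel_size),
      timestamp = as.numeric(timestamp),
      frame_index = as.integer(frame_index),
      field_size = pixel_size * ncol(heights) / 1000
    ),
    class = "scan_frame"
  )
}

#' @export
print.scan_frame <- function(x, ...) {
  cat(sprintf(
    "scan_frame: %d x %d px, %.4g nm/px (%.3g um field), t = %.3f s\n",
    nrow(x$heights), ncol(x$heights), x$pixel_size, x$field_size, x$timestamp
  ))
  invisible(x)
}

#' Experiment-level metadata
#'
#' @param nominal_concentration nominal monomer concentration in nM.
#' @param frame_rate acquisition rate in frames per second.
#' @param buffer_label free-text buffer description.
#' @param series_id identifier for the image series.
#' @return An object of class `experiment_meta`.
#' @export
experiment_meta <- function(nominal_concentration = NA_real_, frame_rate = 1,
                            buffer_label = "", series_id = "series") {
  if (!is.na(nominal_concentration) && nominal_concentration < 0)
    stop("nominal_concentration must be >= 0 nM")
  if (frame_rate <= 0) stop("frame_rate must be > 0 fps")
  structure(
    list(
      nominal_concentration = as.numeric(nominal_concentration),
      frame_rate = as.numeric(frame_rate),
      buffer_label = buffer_label,
      series_id = series_id
    ),
    class = "experiment_meta"
  )
}

#' Time-ordered series of scan frames
#'
#' @param frames list of [scan_frame] objects, time-ordered.
#' @param meta an [experiment_meta].
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(frames, meta = experiment_meta()) {
  if (!length(frames)) stop("a frame_series needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "scan_frame")))
    stop("all frames must be scan_frame objects")
  ts <- vapply(frames, `[[`, numeric(1), "timestamp")
  if (any(diff(ts) <= 0))
    stop("frame timestamps must be strictly increasing (regression at frame ",
         which(diff(ts) <= 0)[1] + 1, ")")
  ps <- vapply(frames, `[[`, numeric(1), "pixel_size")
  dm <- vapply(frames, function(f) dim(f$heights), integer(2))
  if (length(unique(ps)) != 1L || nrow(unique(t(dm))) != 1L)
    stop("all frames in a series must share pixel_size and dimensions")
  structure(list(frames = frames, meta = meta), class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  ts <- vapply(x$frames, `[[`, numeric(1), "timestamp")
  cat(sprintf("frame_series '%s': %d frames, t in [%.1f, %.1f] s, c = %s nM\n",
              x$meta$series_id, length(x$frames), min(ts), max(ts),
              format(x$meta$nominal_concentration)))
  invisible(x)
}

#' @export
length.frame_series <- function(x) length(x$frames)

sidecar_required <- c("series_id", "scan_size_um", "resolution_px",
                      "frame_rate_fps", "start_offset_s", "concentration_nM")

read_sidecar <- function(sidecar) {
  if (!file.exists(sidecar))
    stop("sidecar not found: ", sidecar,
         " (required keys: ", paste(sidecar_required, collapse = ", "), ")")
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  missing <- setdiff(sidecar_required, names(sc))
  if (length(missing))
    stop("sidecar is missing required keys: ", paste(missing, collapse = ", "))
  sc
}

#' Read a calibrated frame series from disk
#'
#' Accepts either a directory of per-frame CSV height grids (files matching
#' `frame_*.csv`, comma-separated nm values, no header) or a multi-page TIFF.
#' A JSON sidecar supplies the physical calibration:
#' `{series_id, scan_size_um, resolution_px, frame_rate_fps, start_offset_s,
#' concentration_nM, timestamps_s?}`. The pixel size is
#' `scan_size_um * 1000 / resolution_px` nm/px. Timestamps are taken from
#' `timestamps_s` when present (the frame rate may change mid-experiment);
#' otherwise `start_offset_s + frame_index / frame_rate_fps`.
#'
#' TIFF pages are read with the values interpreted as nm; if the sidecar has
#' `height_scale` (and optionally `height_offset`), heights are recovered as
#' `stored * height_scale + height_offset`, which is how [write_series()]
#' stores them when asked for TIFF output.
#'
#' @param path directory of CSV grids or a multi-page TIFF file.
#' @param sidecar path to the JSON metadata sidecar; defaults to
#'   `sidecar.json` next to `path`.
#' @return A [frame_series].
#' @export
read_series <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) {
    sidecar <- if (dir.exists(path)) file.path(path, "sidecar.json")
               else file.path(dirname(path), "sidecar.json")
  }
  sc <- read_sidecar(sidecar)
  pixel_size <- sc$scan_size_um * 1000 / sc$resolution_px

  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "^frame_.*\\.csv$",
                             full.names = TRUE))
    if (!length(files)) stop("no frame_*.csv files found in ", path)
    mats <- lapply(seq_along(files), function(i) {
      v <- scan(files[i], sep = ",", quiet = TRUE)
      n <- sc$resolution_px
      if (length(v) %% n != 0)
        stop("non-rectangular frame at index ", i - 1L, " (", files[i], ")")
      # storage precision is float32; snap parsed doubles back to it so the
      # round trip is bit-exact
      matrix(float32_round(v), ncol = n, byrow = TRUE)
    })
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF input requires the 'tiff' package")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    scale <- if (!is.null(sc$height_scale)) sc$height_scale else 1
    offset <- if (!is.null(sc$height_offset)) sc$height_offset else 0
    mats <- lapply(pages, function(p) p * scale + offset)
  }

  nr <- vapply(mats, nrow, integer(1))
  bad <- which(nr != nr[1] | vapply(mats, ncol, integer(1)) != ncol(mats[[1]]))
  if (length(bad))
    stop("non-rectangular frame at index ", bad[1] - 1L)

  n <- length(mats)
  ts <- if (!is.null(sc$timestamps_s)) {
    if (length(sc$timestamps_s) != n)
      stop("timestamps_s has length ", length(sc$timestamps_s),
           " but the series has ", n, " frames")
    as.numeric(sc$timestamps_s)
  } else {
    sc$start_offset_s + (seq_len(n) - 1) / sc$frame_rate_fps
  }
  frames <- lapply(seq_len(n), function(i)
    scan_frame(mats[[i]], pixel_size, timestamp = ts[i], frame_index = i - 1L))
  meta <- experiment_meta(
    nominal_concentration = sc$concentration_nM,
    frame_rate = sc$frame_rate_fps,
    buffer_label = if (!is.null(sc$buffer)) sc$buffer else "",
    series_id = sc$series_id
  )
  frame_series(frames, meta)
}

#' Write a frame series to disk
#'
#' The native format is a directory of per-frame CSV height grids plus a JSON
#' sidecar. Heights are rounded to float32 before formatting with nine
#' significant digits, so a read/write round trip reproduces the float32
#' representation of every height bit-exactly. Per-frame timestamps are
#' always written to the sidecar (`timestamps_s`), so irregular frame rates
#' survive the round trip.
#'
#' @param series a [frame_series].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "frame_series"))
  if (!length(series$frames)) stop("refusing to write a series with 0 frames")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create output directory ", path)
  f1 <- series$frames[[1]]
  sc <- list(
    series_id = series$meta$series_id,
    scan_size_um = f1$field_size,
    resolution_px = ncol(f1$heights),
    frame_rate_fps = series$meta$frame_rate,
    start_offset_s = f1$timestamp,
    concentration_nM = series$meta$nominal_concentration,
    timestamps_s = vapply(series$frames, `[[`, numeric(1), "timestamp")
  )
  jsonlite::write_json(sc, file.path(path, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(series$frames)) {
    h <- float32_round(series$frames[[i]]$heights)
    lines <- apply(h, 1, function(r)
      paste(formatC(r, digits = 9, format = "g"), collapse = ","))
    writeLines(lines, file.path(path, sprintf("frame_%05d.csv", i - 1L)))
  }
  invisible(path)
}

# Round doubles to their nearest float32 value (the storage precision).
float32_round <- function(x) {
  d <- dim(x)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4)
  y <- readBin(rawConnectionValue(con), "numeric", n = length(x), size = 4)
  dim(y) <- d
  y
}

#' Physical coordinates of pixel centers
#'
#' @param frame a [scan_frame].
#' @return list with vectors `x` (per column) and `y` (per row) in nm.
#' @export
pixel_coords <- function(frame) {
  nr <- nrow(frame$heights); nc <- ncol(frame$heights)
  list(x = (seq_len(nc) - 0.5) * frame$pixel_size,
       y = (nr - seq_len(nr) + 0.5) * frame$pixel_size)
}
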