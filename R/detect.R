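#' Detection parameter set
#'
#' Controls thresholding, size filtering and monomer/dimer/cluster
#' classification for one time range of a series. Areas are physical (nm²),
#' so the same parameters work across pixel sizes.
#'
#' @param threshold_mode `"automatic"` (inter-class-variance maximization on
#'   the height histogram) or `"fixed"` (use `threshold_nm`).
#' @param threshold_nm height threshold in nm when `threshold_mode = "fixed"`.
#' @param min_area_nm2 components smaller than this are discarded.
#' @param max_hole_nm2 interior holes up to this area are filled before
#'   measurement (AFM triangles often image with a central cavity).
#' @param class_bands three increasing multipliers of the reference monomer
#'   area: below `class_bands[2]` is a monomer, up to `class_bands[3]` a
#'   dimer, above that a cluster.
#' @param ref_area_nm2 reference monomer area; `NA` means use the median
#'   component area of the field being classified.
#' @param split_monolayer if `TRUE`, cluster-sized components are split into
#'   per-particle seeds by distance-transform local maxima (needed once the
#'   layer closes and connected components stop being single particles).
#' @param lattice_constant_nm expected lattice constant; sets the minimum
#'   seed separation (0.6 × this) used when splitting the monolayer mask.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(threshold_mode = c("automatic", "fixed"),
                             threshold_nm = 1,
                             min_area_nm2 = 2000,
                             max_hole_nm2 = 4000,
                             class_bands = c(0.5, 1.5, 2.5),
                             ref_area_nm2 = NA_real_,
                             split_monolayer = TRUE,
                             lattice_constant_nm = 110) {
  threshold_mode <- match.arg(threshold_mode)
  if (min_area_nm2 <= 0) stop("min_area_nm2 must be > 0")
  if (length(class_bands) != 3 || any(diff(class_bands) <= 0))
    stop("class_bands must be three strictly increasing multipliers")
  structure(
    list(threshold_mode = threshold_mode, threshold_nm = threshold_nm,
         min_area_nm2 = min_area_nm2, max_hole_nm2 = max_hole_nm2,
         class_bands = class_bands, ref_area_nm2 = ref_area_nm2,
         split_monolayer = split_monolayer,
         lattice_constant_nm = lattice_constant_nm),
    class = "detection_params"
  )
}

#' Time-resolved parameter schedule
#'
#' Assigns a [detection_params] set to each time range of a series,
#' mirroring the per-time-range calibration workflow used for real series
#' (early sparse frames and late dense monolayers need different settings).
#'
#' @param ... or `segments`: each segment is `list(t_start, t_end, params)`;
#'   ranges are half-open `[t_start, t_end)`, must not overlap.
#' @param segments alternative list-of-segments form.
#' @return An object of class `param_schedule`.
#' @export
param_schedule <- function(..., segments = NULL) {
  segs <- if (!is.null(segments)) segments else list(...)
  if (!length(segs)) stop("schedule needs at least one segment")
  for (s in segs) {
    if (!all(c("t_start", "t_end", "params") %in% names(s)))
      stop("each segment needs t_start, t_end and params")
    if (!inherits(s$params, "detection_params"))
      stop("segment params must be detection_params objects")
    if (s$t_end <= s$t_start) stop("segment must have t_end > t_start")
  }
  o <- order(vapply(segs, `[[`, numeric(1), "t_start"))
  segs <- segs[o]
  starts <- vapply(segs, `[[`, numeric(1), "t_start")
  ends <- vapply(segs, `[[`, numeric(1), "t_end")
  if (length(segs) > 1 && any(starts[-1] < ends[-length(segs)]))
    stop("schedule segments overlap")
  structure(list(segments = segs), class = "param_schedule")
}

#' Parameters active at a timestamp
#' @param schedule a [param_schedule].
#' @param t timestamp in s.
#' @return The active [detection_params]; errors if `t` is uncovered.
#' @export
params_at <- function(schedule, t) {
  for (s in schedule$segments)
    if (t >= s$t_start && t < s$t_end) return(s$params)
  stop(sprintf("schedule gap: no parameters cover t = %.3f s", t))
}

# Inter-class-variance threshold on the height histogram (automatic mode).
# Otsu always finds a split, even on an all-noise frame or when the
# foreground fraction is tiny (it then splits the noise itself). The split
# is accepted only when it explains a genuinely bimodal histogram: the
# between-class variance fraction eta = w0 w1 (mu1 - mu0)^2 / var equals
# 0.637 for an Otsu split of pure Gaussian noise (a distributional
# constant), so anything above 0.645 indicates real bimodality. Below the
# cut, a robust noise-based threshold (sigma-clipped median + 3 MAD) is
# used instead, which is the right answer precisely in the
# background-dominated regime where Otsu fails; spurious noise pixels
# above it are removed by the min-area filter.
auto_threshold <- function(h) {
  rng <- range(h)
  if (diff(rng) == 0) return(Inf)  # constant frame: nothing above threshold
  img <- EBImage::Image((h - rng[1]) / diff(rng))
  t01 <- EBImage::otsu(img, range = c(0, 1), levels = 256L)
  thr <- rng[1] + t01 * diff(rng)
  fg <- h > thr
  if (any(fg) && !all(fg)) {
    w1 <- mean(fg)
    eta <- w1 * (1 - w1) * (mean(h[fg]) - mean(h[!fg]))^2 /
      stats::var(as.numeric(h))
    if (eta >= 0.645) return(thr)
  }
  # one sigma-clipping pass: plain MAD over-estimates the noise when
  # particles are present
  bg <- h <= stats::median(h) + 3 * stats::mad(h)
  stats::median(h[bg]) + 3 * stats::mad(h[bg])
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass over label pairs.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.integer(lab[-nr, -nc]), as.integer(lab[-1, -1])),   # down-right
    cbind(as.integer(lab[-nr, -1]), as.integer(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

# Fill interior holes up to max_hole_nm2, assigning filled pixels to the
# enclosing component's label.
fill_small_holes <- function(lab, max_hole_nm2, pixel_size) {
  filled <- EBImage::fillHull(lab)
  holes <- filled > 0 & lab == 0
  if (!any(holes)) return(lab)
  hlab <- EBImage::bwlabel(holes)
  hsize <- tabulate(hlab[hlab > 0])
  keep <- which(hsize * pixel_size^2 <= max_hole_nm2)
  if (!length(keep)) return(lab)
  sel <- hlab > 0 & hlab %in% keep
  lab[sel] <- filled[sel]
  lab
}

# Watershed segmentation of the distance transform inside merged (cluster
# sized) components: yields one catchment basin per particle once the layer
# closes and connected components stop being individual triangles. The
# tolerance scales with the expected particle radius in pixels.
split_monolayer_mask <- function(mask, lattice_constant_nm, pixel_size) {
  d <- EBImage::distmap(mask)
  tol <- max(0.1 * lattice_constant_nm / pixel_size, 0.5)
  EBImage::watershed(d, tolerance = tol, ext = 1)
}

#' Segment particles in a flattened frame
#'
#' Thresholds the height image (automatic inter-class-variance or fixed nm
#' threshold), groups above-threshold pixels into 8-connected components,
#' fills interior holes up to `max_hole_nm2`, discards components below
#' `min_area_nm2` and reports intensity-weighted centroids in physical nm.
#' Surface coverage is the above-threshold pixel fraction after filtering —
#' a definition that stays meaningful when particles merge into a closed
#' monolayer and counting fails. Cluster-sized components are optionally
#' split into per-particle seeds from distance-transform peaks so that
#' lattice analysis has per-triangle positions at monolayer coverage.
#'
#' @param frame a flattened [scan_frame].
#' @param params a [detection_params].
#' @return An object of class `particle_field`: `particles` data frame
#'   (`x_nm`, `y_nm`, `area_nm2`, `mean_height_nm`, `class`, `component`),
#'   `frame_area_um2`, `coverage`, `timestamp`, `threshold_nm`,
#'   `dimer_fraction` (filled by [classify_particles()]).
#' @export
detect_particles <- function(frame, params = detection_params()) {
  stopifnot(inherits(frame, "scan_frame"))
  h <- frame$heights
  if (any(is.nan(h))) stop("frame contains NaN pixels")
  ps <- frame$pixel_size
  px_area <- ps^2
  thr <- if (params$threshold_mode == "fixed") params$threshold_nm
         else auto_threshold(h)
  mask <- h > thr
  nr <- nrow(h); nc <- ncol(h)
  frame_area_um2 <- (nr * ps / 1000) * (nc * ps / 1000)

  empty <- function() {
    structure(list(
      particles = data.frame(x_nm = numeric(0), y_nm = numeric(0),
                             area_nm2 = numeric(0), mean_height_nm = numeric(0),
                             class = character(0), component = integer(0)),
      frame_area_um2 = frame_area_um2, coverage = 0,
      timestamp = frame$timestamp, threshold_nm = thr,
      dimer_fraction = NA_real_), class = "particle_field")
  }
  if (!any(mask)) return(empty())

  lab <- label8(mask)
  lab <- fill_small_holes(lab, params$max_hole_nm2, ps)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * px_area >= params$min_area_nm2)
  if (!length(keep)) return(empty())
  drop_sel <- lab > 0 & !(lab %in% keep)
  lab[drop_sel] <- 0L

  coverage <- sum(lab > 0) / (nr * nc)
  xy <- pixel_coords(frame)
  Xmat <- matrix(xy$x, nr, nc, byrow = TRUE)
  Ymat <- matrix(xy$y, nr, nc)

  comps <- keep
  w <- pmax(h, 0)
  parts <- lapply(comps, function(cid) {
    sel <- lab == cid
    wi <- w[sel]
    if (sum(wi) == 0) wi <- rep(1, sum(sel))
    data.frame(
      x_nm = sum(Xmat[sel] * wi) / sum(wi),
      y_nm = sum(Ymat[sel] * wi) / sum(wi),
      area_nm2 = sum(sel) * px_area,
      mean_height_nm = mean(h[sel]),
      class = "unclassified",
      component = cid
    )
  })
  particles <- do.call(rbind, parts)

  if (isTRUE(params$split_monolayer)) {
    ref <- params$ref_area_nm2
    if (is.na(ref)) ref <- stats::median(particles$area_nm2)
    big_cids <- particles$component[
      particles$area_nm2 > params$class_bands[3] * ref]
    if (length(big_cids)) {
      # use the raw (pre-hole-filling) mask: the pores between touching
      # particles are exactly what the watershed needs to separate them
      bigmask <- mask & matrix(lab %in% big_cids, nr, nc)
      ws <- split_monolayer_mask(bigmask, params$lattice_constant_nm, ps)
      nseg <- max(ws)
      if (nseg > length(big_cids)) {
        seg <- ws[ws > 0]
        idx <- which(ws > 0, arr.ind = TRUE)
        wt <- pmax(h[ws > 0], 0) + 1e-12
        area_px <- tabulate(seg, nseg)
        sx <- vapply(split(wt * (idx[, 2] - 0.5) * ps, seg), sum, numeric(1)) /
              vapply(split(wt, seg), sum, numeric(1))
        sy <- vapply(split(wt * (nr - idx[, 1] + 0.5) * ps, seg), sum,
                     numeric(1)) /
              vapply(split(wt, seg), sum, numeric(1))
        mh <- vapply(split(h[ws > 0], seg), mean, numeric(1))
        comp_of <- vapply(split(lab[ws > 0], seg),
                          function(v) as.integer(stats::median(v)),
                          integer(1))
        new_rows <- data.frame(x_nm = sx, y_nm = sy,
                               area_nm2 = area_px * px_area,
                               mean_height_nm = mh,
                               class = "unclassified", component = comp_of)
        new_rows <- new_rows[new_rows$area_nm2 >= params$min_area_nm2, ]
        if (nrow(new_rows) > 1)
          particles <- rbind(
            particles[!(particles$component %in% big_cids), ], new_rows)
      }
    }
  }
  rownames(particles) <- NULL

  structure(list(particles = particles, frame_area_um2 = frame_area_um2,
                 coverage = coverage, timestamp = frame$timestamp,
                 threshold_nm = thr, dimer_fraction = NA_real_),
            class = "particle_field")
}

#' @export
print.particle_field <- function(x, ...) {
  cat(sprintf("particle_field: %d particles, coverage %.3f, t = %.1f s\n",
              nrow(x$particles), x$coverage, x$timestamp))
  invisible(x)
}

#' Classify particles as monomer, dimer or cluster by area band
#'
#' Bands are multipliers of the reference monomer area (default: below 1.5x
#' monomer, 1.5-2.5x dimer, above 2.5x cluster). Adds the dimer fraction
#' dimers / (monomers + dimers) to the field summary; an empty field gets a
#' missing dimer fraction.
#'
#' @param field a [particle_field].
#' @param reference_monomer_area reference area in nm²; `NULL` means the
#'   median component area of this field.
#' @param class_bands three increasing band-edge multipliers.
#' @return The field with `class` labels and `dimer_fraction` filled in.
#' @export
classify_particles <- function(field, reference_monomer_area = NULL,
                               class_bands = c(0.5, 1.5, 2.5)) {
  stopifnot(inherits(field, "particle_field"))
  p <- field$particles
  if (!nrow(p)) {
    field$dimer_fraction <- NA_real_
    return(field)
  }
  ref <- reference_monomer_area
  if (is.null(ref) || is.na(ref)) ref <- stats::median(p$area_nm2)
  if (ref <= 0) stop("reference_monomer_area must be > 0")
  ratio <- p$area_nm2 / ref
  p$class <- ifelse(ratio < class_bands[2], "monomer",
             ifelse(ratio < class_bands[3], "dimer", "cluster"))
  nm <- sum(p$class == "monomer"); nd <- sum(p$class == "dimer")
  field$particles <- p
  field$dimer_fraction <- if (nm + nd > 0) nd / (nm + nd) else NA_real_
  field
}

# Flatten + detect + classify for every frame of a series, with the
# parameter set taken from the schedule at each frame's timestamp.
detect_series <- function(series, schedule, flatten_order = 1L,
                          window_deg = 5, reference_monomer_area = NULL) {
  stopifnot(inherits(series, "frame_series"),
            inherits(schedule, "param_schedule"))
  ts <- vapply(series$frames, `[[`, numeric(1), "timestamp")
  for (t in ts) params_at(schedule, t)  # fail fast on schedule gaps
  lapply(series$frames, function(f) {
    p <- params_at(schedule, f$timestamp)
    ff <- flatten_lines(level_plane(f), order = flatten_order)
    classify_particles(detect_particles(ff, p),
                       reference_monomer_area = reference_monomer_area,
                       class_bands = p$class_bands)
  })
}

#' Coverage vs time for a frame series
#'
#' Flattens each frame, detects and classifies particles with the schedule's
#' parameters, and returns the time-ordered surface coverage trace.
#'
#' @param series a [frame_series].
#' @param schedule a [param_schedule] covering all timestamps.
#' @param flatten_order polynomial order for [flatten_lines()].
#' @param keep_fields if `TRUE`, attach the per-frame particle fields as
#'   attribute `"fields"` (needed by [order_series()] callers that reuse the
#'   detections).
#' @return A `coverage_series` object (see [as_coverage_series()]) with
#'   extra vectors `n_particles` and `dimer_fraction`.
#' @export
coverage_series <- function(series, schedule, flatten_order = 1L,
                            keep_fields = FALSE) {
  fields <- detect_series(series, schedule, flatten_order)
  cs <- as_coverage_series(
    t = vapply(fields, `[[`, numeric(1), "timestamp"),
    theta = vapply(fields, `[[`, numeric(1), "coverage"),
    series_id = series$meta$series_id,
    concentration = series$meta$nominal_concentration
  )
  cs$n_particles <- vapply(fields, function(f) nrow(f$particles), integer(1))
  cs$dimer_fraction <- vapply(fields, `[[`, numeric(1), "dimer_fraction")
  if (keep_fields) attr(cs, "fields") <- fields
  cs
}
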