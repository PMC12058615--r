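#' Delaunay triangulation with interior angles
#'
#' Triangulates particle centroids and computes all interior angles in
#' degrees. Triangles with at least one edge on the convex hull are flagged
#' so callers can include or exclude boundary triangles. A deterministic
#' sub-nanometre jitter (1e-6 nm, keyed to point index) is applied before
#' triangulation so that exactly cocircular configurations — ubiquitous on
#' synthetic perfect lattices — triangulate stably and reproducibly.
#'
#' Angles are computed from edge vectors via the arc-cosine of normalized
#' dot products clamped to \[-1, 1\].
#'
#' @param points two-column matrix or data frame of centroids (x, y) in nm.
#' @param frame_area_um2 analyzed area in µm² (carried along for
#'   normalization; optional).
#' @return An object of class `triangulation`: `points`, `triangles`
#'   (index triples, one row per triangle), `angles` (matrix, degrees, one
#'   column per triangle vertex), `hull_flags` (logical per triangle),
#'   `frame_area_um2`.
#' @export
triangulate_angles <- function(points, frame_area_um2 = NA_real_) {
  P <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(P) < 3) stop("need at least 3 points to triangulate")
  i <- seq_len(nrow(P))
  # Tie-breaking jitter for the triangulation only: it decides how exactly
  # cocircular/collinear configurations (perfect lattices) are triangulated,
  # deterministically via the point index. Angles are computed from the
  # unjittered coordinates, so exact lattices keep exact 60 degree angles.
  amp <- max(1e-6, 1e-7 * max(diff(range(P[, 1])), diff(range(P[, 2]))))
  Pj <- P + amp * cbind(sin(i * 12.9898), cos(i * 78.2331))
  dd <- deldir::deldir(Pj[, 1], Pj[, 2], suppressMsge = TRUE)
  tri <- deldir::triMat(dd)
  if (!is.null(tri) && !is.matrix(tri)) tri <- matrix(tri, ncol = 3)
  if (is.null(tri) || nrow(tri) == 0)
    stop("points are collinear: no triangles in the Delaunay triangulation")

  angles_of <- function(tri) {
    ang <- matrix(NA_real_, nrow(tri), 3)
    for (v in 1:3) {
      A <- P[tri[, v], , drop = FALSE]
      B <- P[tri[, v %% 3 + 1], , drop = FALSE]
      C <- P[tri[, (v + 1) %% 3 + 1], , drop = FALSE]
      u <- B - A; w <- C - A
      cosang <- rowSums(u * w) /
        (sqrt(rowSums(u^2)) * sqrt(rowSums(w^2)))
      ang[, v] <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    }
    ang
  }
  ang <- angles_of(tri)
  # drop zero-area sliver artifacts that deldir emits for exactly collinear
  # runs of points (they come in overlapping pairs and are not simplices)
  keep <- apply(ang, 1, max) < 180 - 1e-5
  tri <- tri[keep, , drop = FALSE]
  ang <- ang[keep, , drop = FALSE]
  if (!nrow(tri))
    stop("points are collinear: no triangles in the Delaunay triangulation")

  # hull triangles: any edge used by exactly one triangle
  n <- nrow(P)
  ekey <- function(a, b) pmin(a, b) * (n + 1) + pmax(a, b)
  edges <- c(ekey(tri[, 1], tri[, 2]), ekey(tri[, 2], tri[, 3]),
             ekey(tri[, 1], tri[, 3]))
  cnt <- table(edges)
  boundary <- as.numeric(names(cnt)[cnt == 1])
  hull <- matrix(edges %in% boundary, nrow(tri), 3)
  structure(list(points = P, triangles = tri, angles = ang,
                 hull_flags = rowSums(hull) > 0,
                 frame_area_um2 = frame_area_um2),
            class = "triangulation")
}

#' @export
print.triangulation <- function(x, ...) {
  cat(sprintf("triangulation: %d points, %d triangles (%d on hull)\n",
              nrow(x$points), nrow(x$triangles), sum(x$hull_flags)))
  invisible(x)
}

#' Delaunay-angle order parameter n(Theta60)
#'
#' Counts interior angles within the half-open window
#' `[60 - window_deg, 60 + window_deg)` degrees and normalizes by the
#' analyzed area in µm². A perfect triangular lattice maximizes this count
#' (six 60° angles meet at every interior point), while disordered
#' arrangements spread the angle distribution away from 60°; the parameter
#' is less sensitive to image-boundary effects than nearest-neighbor-based
#' order measures. The half-open window prevents double counting at exact
#' bin edges.
#'
#' @param tri a [triangulate_angles()] result.
#' @param window_deg half-width of the 60° window in degrees (default 5).
#' @param area_um2 analyzed area in µm²; defaults to the triangulation's.
#' @param include_hull count angles of hull triangles too (default `TRUE`;
#'   set `FALSE` to restrict to triangles fully interior to the image).
#' @return An object of class `order_result`: `n_theta60` (count per µm²),
#'   `n_angles_60`, `n_angles_total`, `window_deg`, `analyzed_area_um2`,
#'   `angle_histogram` (data frame `bin_start_deg`, `count`, bins of width
#'   `window_deg` from 0 to 180).
#' @export
order_parameter <- function(tri, window_deg = 5, area_um2 = NULL,
                            include_hull = TRUE) {
  stopifnot(inherits(tri, "triangulation"))
  if (window_deg <= 0) stop("window_deg must be > 0")
  if (is.null(area_um2)) area_um2 <- tri$frame_area_um2
  if (is.na(area_um2) || area_um2 <= 0)
    stop("a positive analyzed area (um^2) is required")
  ang <- if (include_hull) tri$angles
         else tri$angles[!tri$hull_flags, , drop = FALSE]
  a <- as.numeric(ang)
  in_win <- a >= 60 - window_deg & a < 60 + window_deg
  breaks <- seq(0, 180 + window_deg, by = window_deg)
  hg <- graphics::hist(pmin(a, 180), breaks = breaks, plot = FALSE,
                       right = FALSE)
  structure(list(
    n_theta60 = sum(in_win) / area_um2,
    n_angles_60 = sum(in_win),
    n_angles_total = length(a),
    window_deg = window_deg,
    analyzed_area_um2 = area_um2,
    angle_histogram = data.frame(bin_start_deg = hg$breaks[-length(hg$breaks)],
                                 count = hg$counts)
  ), class = "order_result")
}

#' @export
print.order_result <- function(x, ...) {
  cat(sprintf(
    "order_result: n(Theta60) = %.1f per um^2 (%d of %d angles in 60 +/- %g deg, area %.3g um^2)\n",
    x$n_theta60, x$n_angles_60, x$n_angles_total, x$window_deg,
    x$analyzed_area_um2))
  invisible(x)
}

#' Order parameter over a frame series
#'
#' Runs detection per frame (via the schedule), triangulates the detected
#' centroids and evaluates n(Theta60) per frame. Frames with fewer than 3
#' particles yield n(Theta60) = 0 by convention.
#'
#' @param series a [frame_series].
#' @param schedule a [param_schedule].
#' @param window_deg window half-width in degrees.
#' @param flatten_order polynomial order for line flattening.
#' @param include_hull include hull-triangle angles in the count.
#' @param fields optional pre-computed list of particle fields (as attached
#'   by `coverage_series(..., keep_fields = TRUE)`) to avoid re-detection.
#' @return data frame: `t_s`, `n_particles`, `n_angles_total`,
#'   `n_angles_60`, `n_theta60_per_um2`.
#' @export
order_series <- function(series, schedule, window_deg = 5,
                         flatten_order = 1L, include_hull = TRUE,
                         fields = NULL) {
  if (is.null(fields))
    fields <- detect_series(series, schedule, flatten_order)
  rows <- lapply(fields, function(f) {
    n <- nrow(f$particles)
    if (n < 3) {
      return(data.frame(t_s = f$timestamp, n_particles = n,
                        n_angles_total = 0L, n_angles_60 = 0L,
                        n_theta60_per_um2 = 0))
    }
    tri <- triangulate_angles(f$particles[, c("x_nm", "y_nm")],
                              frame_area_um2 = f$frame_area_um2)
    o <- order_parameter(tri, window_deg = window_deg,
                         include_hull = include_hull)
    data.frame(t_s = f$timestamp, n_particles = n,
               n_angles_total = o$n_angles_total,
               n_angles_60 = o$n_angles_60,
               n_theta60_per_um2 = o$n_theta60)
  })
  do.call(rbind, rows)
}
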