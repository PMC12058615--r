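#' Construct a synthetic particle scene
#'
#' Ground-truth container for generated scenes: centroid positions in nm,
#' per-particle orientation and class, plus the generation parameters.
#'
#' @param positions two-column matrix/data frame of (x, y) in nm.
#' @param orientations_deg per-particle orientation in degrees.
#' @param class_labels per-particle `"monomer"` or `"dimer"`.
#' @param field_um field side length in µm.
#' @param params list of generation parameters (kept for provenance).
#' @return An object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(positions, orientations_deg = NULL,
                            class_labels = NULL, field_um = 1,
                            params = list()) {
  P <- as.matrix(positions)
  if (ncol(P) < 2) P <- matrix(numeric(0), 0, 2)
  colnames(P) <- c("x_nm", "y_nm")[1:2]
  np <- nrow(P)
  if (is.null(orientations_deg)) orientations_deg <- rep(0, np)
  if (is.null(class_labels)) class_labels <- rep("monomer", np)
  structure(list(positions = P, orientations_deg = orientations_deg,
                 class_labels = class_labels, field_um = field_um,
                 params = params),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d particles in %.3g x %.3g um field\n",
              nrow(x$positions), x$field_um, x$field_um))
  invisible(x)
}

# Triangular-lattice sites covering [0, L] x [0, L] nm after rotation by
# theta (degrees) about the field center.
lattice_sites <- function(a, L, theta_deg = 0) {
  ry <- a * sqrt(3) / 2
  # generate over an enlarged box so rotation never exposes gaps
  half <- L / 2
  reach <- half * sqrt(2) + 2 * a
  rows <- seq(-ceiling(reach / ry), ceiling(reach / ry))
  pts <- do.call(rbind, lapply(rows, function(r) {
    y <- r * ry
    xoff <- (r %% 2) * a / 2
    xs <- seq(-ceiling((reach + a) / a), ceiling((reach + a) / a)) * a + xoff
    cbind(xs, y)
  }))
  th <- theta_deg * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts <- pts %*% t(Rm)
  pts <- cbind(pts[, 1] + half, pts[, 2] + half)
  pts[pts[, 1] >= 0 & pts[, 1] < L & pts[, 2] >= 0 & pts[, 2] < L, ,
      drop = FALSE]
}

#' Generate a (possibly disordered) triangular-lattice scene
#'
#' Builds centroids of a hexagonally close-packed layer: a triangular
#' lattice with spacing `a`, optional independent Gaussian positional
#' jitter per point, vacancies removed at a given rate, and grains realized
#' as Voronoi regions of `grain_count` random seed points, each grain with
#' its own lattice rotation. Deterministic given `seed`.
#'
#' Orientations alternate by sublattice parity (up/down triangles), the
#' packing that tiles the plane with triangular particles.
#'
#' @param a lattice constant in nm (default 110).
#' @param field_um field side in µm (default 1); must be at least `3 a`.
#' @param jitter_sigma positional jitter s.d. in nm.
#' @param vacancy_rate fraction of sites removed at random, in \[0, 1).
#' @param grain_count number of lattice grains (1 = single crystal).
#' @param orientation_deg lattice rotation of the first grain.
#' @param seed integer seed.
#' @return A `synthetic_scene`.
#' @export
make_lattice_scene <- function(a = 110, field_um = 1, jitter_sigma = 0,
                               vacancy_rate = 0, grain_count = 1L,
                               orientation_deg = 0, seed = 1L) {
  if (a <= 0) stop("lattice constant a must be > 0")
  L <- field_um * 1000
  if (L < 3 * a) stop("field must be at least 3 lattice constants wide")
  if (vacancy_rate >= 1) stop("vacancy_rate must be < 1")
  with_seed(seed, {
    if (grain_count <= 1) {
      pts <- lattice_sites(a, L, orientation_deg)
      rot <- rep(orientation_deg, nrow(pts))
    } else {
      seeds_xy <- matrix(stats::runif(2 * grain_count, 0, L), ncol = 2)
      rots <- c(orientation_deg,
                stats::runif(grain_count - 1, 0, 60))
      all_pts <- list(); all_rot <- list()
      for (g in seq_len(grain_count)) {
        p <- lattice_sites(a, L, rots[g])
        d2 <- outer(p[, 1], seeds_xy[, 1], "-")^2 +
              outer(p[, 2], seeds_xy[, 2], "-")^2
        mine <- max.col(-d2) == g
        all_pts[[g]] <- p[mine, , drop = FALSE]
        all_rot[[g]] <- rep(rots[g], sum(mine))
      }
      pts <- do.call(rbind, all_pts)
      rot <- unlist(all_rot)
    }
    n <- nrow(pts)
    if (vacancy_rate > 0) {
      keep <- stats::runif(n) >= vacancy_rate
      pts <- pts[keep, , drop = FALSE]
      rot <- rot[keep]
      n <- nrow(pts)
    }
    if (jitter_sigma > 0)
      pts <- pts + matrix(stats::rnorm(2 * n, sd = jitter_sigma), ncol = 2)
    # alternate up/down orientation by row parity of the unrotated lattice
    orient <- rot + 60 * (seq_len(n) %% 2)
    synthetic_scene(pts, orient, rep("monomer", n), field_um,
                    params = list(a = a, jitter_sigma = jitter_sigma,
                                  vacancy_rate = vacancy_rate,
                                  grain_count = grain_count, seed = seed))
  })
}

#' Homogeneous Poisson (CSR) scene
#'
#' Complete-spatial-randomness baseline for the order parameter: point
#' count drawn from Poisson(density x area), positions uniform.
#'
#' @param density_per_um2 intensity in points per µm².
#' @param field_um field side in µm.
#' @param seed integer seed.
#' @return A `synthetic_scene`.
#' @export
make_poisson_scene <- function(density_per_um2, field_um = 1, seed = 1L) {
  if (density_per_um2 < 0) stop("density must be >= 0")
  L <- field_um * 1000
  with_seed(seed, {
    n <- stats::rpois(1, density_per_um2 * field_um^2)
    pts <- matrix(stats::runif(2 * n, 0, L), ncol = 2)
    synthetic_scene(pts, rep(0, n), rep("monomer", n), field_um,
                    params = list(density = density_per_um2, seed = seed))
  })
}

#' Randomly packed scene with exclusion and planted dimers
#'
#' Places particles by random sequential adsorption (uniform proposals,
#' rejected within `min_sep_nm` of an accepted particle) until `n_entities`
#' are placed or proposals are exhausted. A fraction of entities are dimers:
#' two triangles in vertex-to-vertex contact (centroids `2 * side/sqrt(3)`
#' apart, facing each other), the geometry produced by blunt-end stacking
#' at triangle tips. Ground truth for detection and dimer-fraction tests.
#'
#' @param n_entities number of entities (a dimer counts once) to place.
#' @param field_um field side in µm.
#' @param min_sep_nm minimum centroid distance to previously placed
#'   particles (dimer partners exempt from each other).
#' @param dimer_fraction fraction of entities planted as dimers.
#' @param side_nm triangle side length (sets the dimer contact distance
#'   and the edge margin keeping triangles fully inside the field).
#' @param seed integer seed.
#' @return A `synthetic_scene`; `params$true_dimer_fraction` holds the
#'   planted entity-level dimer fraction.
#' @export
make_adsorbed_scene <- function(n_entities, field_um = 1, min_sep_nm = 130,
                                dimer_fraction = 0, side_nm = 120,
                                seed = 1L) {
  L <- field_um * 1000
  margin <- 0.7 * side_nm  # triangles stay fully inside the frame
  # vertex-to-vertex centroid distance, slightly overlapped so the pair
  # always rasterizes as one connected component
  R2 <- 0.95 * 2 * side_nm / sqrt(3)
  with_seed(seed, {
    pos <- matrix(numeric(0), 0, 2)
    orient <- numeric(0); cls <- character(0)
    n_dimers <- 0L; placed <- 0L; tries <- 0L
    while (placed < n_entities && tries < 200 * n_entities) {
      tries <- tries + 1L
      want_dimer <- stats::runif(1) < dimer_fraction
      p <- stats::runif(2, margin, L - margin)
      phi <- stats::runif(1, 0, 360)
      if (want_dimer) {
        u <- (phi + 90) * pi / 180  # direction of a vertex of particle 1
        q <- p + R2 * c(cos(u), sin(u))
        if (any(q < margin) || any(q >= L - margin)) next
        new <- rbind(p, q)
        newor <- c(phi, phi + 180)
        newcls <- c("dimer", "dimer")
      } else {
        new <- rbind(p)
        newor <- phi
        newcls <- "monomer"
      }
      ok <- TRUE
      if (nrow(pos)) {
        for (r in seq_len(nrow(new))) {
          d2 <- (pos[, 1] - new[r, 1])^2 + (pos[, 2] - new[r, 2])^2
          if (min(d2) < min_sep_nm^2) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      pos <- rbind(pos, new)
      orient <- c(orient, newor)
      cls <- c(cls, newcls)
      placed <- placed + 1L
      if (want_dimer) n_dimers <- n_dimers + 1L
    }
    synthetic_scene(pos, orient, cls, field_um,
                    params = list(min_sep_nm = min_sep_nm,
                                  side_nm = side_nm, seed = seed,
                                  n_entities = placed,
                                  n_dimers = n_dimers,
                                  true_dimer_fraction = n_dimers / placed))
  })
}

#' Render a scene as an AFM-like height frame
#'
#' Rasterizes an equilateral triangle (side `side_nm`, height `height_nm`)
#' at each scene position/orientation on a zero background, then applies a
#' Gaussian blur (a simple proxy for tip broadening), per-pixel Gaussian
#' height noise and per-scan-line offsets. The painted pixel fraction
#' before noise is attached as attribute `"painted_fraction"` (ground truth
#' for coverage tests).
#'
#' @param scene a `synthetic_scene`.
#' @param pixel_size nm/px (default 5, i.e. 200 px across a 1 µm field).
#' @param noise_sigma per-pixel Gaussian height noise s.d. in nm.
#' @param scanline_sigma per-line offset s.d. in nm.
#' @param blur_nm Gaussian blur s.d. in nm (0 disables).
#' @param side_nm triangle side in nm (default 120).
#' @param height_nm triangle height in nm (default 2).
#' @param timestamp frame timestamp in s.
#' @param frame_index frame number.
#' @param seed optional seed for the noise draws.
#' @return A [scan_frame].
#' @export
render_frame <- function(scene, pixel_size = 5, noise_sigma = 0,
                         scanline_sigma = 0, blur_nm = 0, side_nm = 120,
                         height_nm = 2, timestamp = 0, frame_index = 0L,
                         seed = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (side_nm < 2 * pixel_size)
    stop("particle side below 2 pixels: unresolvable at this pixel size")
  L <- scene$field_um * 1000
  n <- round(L / pixel_size)
  h <- matrix(0, n, n)
  P <- scene$positions
  Rv <- side_nm / sqrt(3)  # centroid-to-vertex distance
  for (p in seq_len(nrow(P))) {
    cx <- P[p, 1]; cy <- P[p, 2]
    va <- (scene$orientations_deg[p] + c(90, 210, 330)) * pi / 180
    vx <- cx + Rv * cos(va); vy <- cy + Rv * sin(va)
    jlo <- max(1L, floor(min(vx) / pixel_size)); jhi <- min(n, ceiling(max(vx) / pixel_size) + 1L)
    ilo <- max(1L, floor((n * pixel_size - max(vy)) / pixel_size)); ihi <- min(n, ceiling((n * pixel_size - min(vy)) / pixel_size) + 1L)
    if (jlo > jhi || ilo > ihi) next
    jj <- jlo:jhi; ii <- ilo:ihi
    px <- (jj - 0.5) * pixel_size
    py <- (n - ii + 0.5) * pixel_size
    X <- matrix(px, length(ii), length(jj), byrow = TRUE)
    Y <- matrix(py, length(ii), length(jj))
    # barycentric sign test against the three edges
    inside <- rep(TRUE, length(X))
    dim(inside) <- dim(X)
    for (e in 1:3) {
      x1 <- vx[e]; y1 <- vy[e]
      x2 <- vx[e %% 3 + 1]; y2 <- vy[e %% 3 + 1]
      s <- (x2 - x1) * (Y - y1) - (y2 - y1) * (X - x1)
      inside <- inside & s >= 0
    }
    blk <- h[ii, jj, drop = FALSE]
    blk[inside] <- pmax(blk[inside], height_nm)
    h[ii, jj] <- blk
  }
  painted <- mean(h > 0)
  if (blur_nm > 0)
    h <- as.matrix(EBImage::gblur(h, sigma = blur_nm / pixel_size))
  add_noise <- function() {
    if (noise_sigma > 0)
      h <<- h + matrix(stats::rnorm(n * n, sd = noise_sigma), n, n)
    if (scanline_sigma > 0)
      h <<- h + stats::rnorm(n, sd = scanline_sigma)  # recycled per row (scan line)
  }
  if (!is.null(seed)) with_seed(seed, add_noise()) else add_noise()
  out <- scan_frame(h, pixel_size, timestamp = timestamp,
                    frame_index = frame_index)
  attr(out, "painted_fraction") <- painted
  out
}

#' Simulation parameters for assembly
#'
#' @param target_concentration nominal monomer concentration c in nM.
#' @param injection_lag_tau diffusion lag time constant tau_d in s: the
#'   effective near-surface concentration rises as
#'   `c * (1 - exp(-t / tau_d))`, modeling transport of monomers through
#'   the liquid-cell volume after injection.
#' @param attempt_rate_per_nM adsorption attempt rate per µm² per s per nM.
#' @param max_flux_per_um2 ceiling on the arrival rate (attempts per µm²
#'   per s) regardless of concentration: transport through the liquid-cell
#'   volume can deliver only so many particles per unit time, which is what
#'   makes the time to monolayer concentration-independent once the nominal
#'   concentration saturates the transport capacity. `Inf` disables the cap
#'   (purely reaction-limited arrival).
#' @param exclusion_radius minimum centroid distance to an adsorbed
#'   particle for an attempt to succeed (nm).
#' @param desorption_prob per-particle, per-frame desorption probability.
#' @param relaxation_prob per-particle, per-frame probability of snapping
#'   to the nearest free site of the reference lattice (surface-mobility
#'   proxy that anneals defects).
#' @param duration_s simulated time span.
#' @param fps frames per second.
#' @param field_um field side in µm.
#' @param side_nm triangle side (for ground-truth coverage).
#' @param lattice_a reference lattice constant for relaxation (nm).
#' @param seed integer seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(target_concentration = 6, injection_lag_tau = 60,
                       attempt_rate_per_nM = 0.5, max_flux_per_um2 = Inf,
                       exclusion_radius = 100,
                       desorption_prob = 0, relaxation_prob = 0,
                       duration_s = 600, fps = 1, field_um = 1,
                       side_nm = 120, lattice_a = 110, seed = 1L) {
  stopifnot(target_concentration >= 0, injection_lag_tau >= 0,
            attempt_rate_per_nM >= 0, max_flux_per_um2 > 0,
            exclusion_radius >= 0,
            desorption_prob >= 0, desorption_prob <= 1,
            relaxation_prob >= 0, relaxation_prob <= 1,
            duration_s > 0, fps > 0)
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate lattice assembly by random sequential adsorption
#'
#' Discrete-time simulation at `1/fps` resolution. Each frame draws a
#' Poisson number of adsorption attempts with rate
#' `attempt_rate_per_nM * c * (1 - exp(-t / tau_d)) * area`; an attempt at
#' a uniform random position succeeds iff no adsorbed particle lies within
#' the exclusion radius. Adsorbed particles desorb independently with
#' `desorption_prob` per frame, and with `relaxation_prob` snap to the
#' nearest free site of a reference triangular lattice — the simulator's
#' analogue of surface mobility annealing lattice defects. Deterministic
#' given the seed.
#'
#' @param params a [sim_params].
#' @return An object of class `assembly_sim`: `params`, `summary` data
#'   frame (`t_s`, `n_particles`, `theta_true` — analytic painted fraction
#'   `n * triangle_area / field_area`), and `frames`, a list of per-frame
#'   position matrices (nm).
#' @export
simulate_assembly <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  L <- params$field_um * 1000
  area_um2 <- params$field_um^2
  tri_area <- sqrt(3) / 4 * params$side_nm^2
  dt <- 1 / params$fps
  nframes <- ceiling(params$duration_s * params$fps)
  sites <- lattice_sites(params$lattice_a, L, 0)
  with_seed(params$seed, {
    pos <- matrix(numeric(0), 0, 2)
    frames <- vector("list", nframes)
    summ <- data.frame(t_s = numeric(nframes), n_particles = integer(nframes),
                       theta_true = numeric(nframes))
    for (fi in seq_len(nframes)) {
      t <- fi * dt
      c_eff <- params$target_concentration *
        if (params$injection_lag_tau > 0) (1 - exp(-t / params$injection_lag_tau)) else 1
      flux <- min(params$attempt_rate_per_nM * c_eff, params$max_flux_per_um2)
      lambda <- flux * area_um2 * dt
      n_att <- stats::rpois(1, lambda)
      if (n_att > 0) {
        props <- matrix(stats::runif(2 * n_att, 0, L), ncol = 2)
        for (r in seq_len(n_att)) {
          if (nrow(pos)) {
            d2 <- (pos[, 1] - props[r, 1])^2 + (pos[, 2] - props[r, 2])^2
            if (min(d2) < params$exclusion_radius^2) next
          }
          pos <- rbind(pos, props[r, ])
        }
      }
      if (params$desorption_prob > 0 && nrow(pos)) {
        keep <- stats::runif(nrow(pos)) >= params$desorption_prob
        pos <- pos[keep, , drop = FALSE]
      }
      if (params$relaxation_prob > 0 && nrow(pos)) {
        movers <- which(stats::runif(nrow(pos)) < params$relaxation_prob)
        for (m in movers) {
          d2s <- (sites[, 1] - pos[m, 1])^2 + (sites[, 2] - pos[m, 2])^2
          for (s in order(d2s)[1:min(5, nrow(sites))]) {
            cand <- sites[s, ]
            d2 <- (pos[-m, 1] - cand[1])^2 + (pos[-m, 2] - cand[2])^2
            if (!length(d2) || min(d2) >= params$exclusion_radius^2) {
              pos[m, ] <- cand
              break
            }
          }
        }
      }
      frames[[fi]] <- pos
      summ$t_s[fi] <- t
      summ$n_particles[fi] <- nrow(pos)
      summ$theta_true[fi] <- min(nrow(pos) * tri_area / (L * L), 1)
    }
    structure(list(params = params, summary = summ, frames = frames),
              class = "assembly_sim")
  })
}

#' @export
print.assembly_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "assembly_sim: %d frames, final n = %d (theta_true = %.3f) at c = %g nM\n",
    nrow(s), utils::tail(s$n_particles, 1), utils::tail(s$theta_true, 1),
    x$params$target_concentration))
  invisible(x)
}

#' Scene snapshot of a simulated frame
#'
#' @param sim an [simulate_assembly()] result.
#' @param frame_i frame number.
#' @return A `synthetic_scene` of that frame's particle positions, with
#'   uniform pseudo-random orientations keyed to position (deterministic).
#' @export
sim_scene <- function(sim, frame_i) {
  pos <- sim$frames[[frame_i]]
  n <- nrow(pos)
  orient <- if (n) (pos[, 1] * 7.13 + pos[, 2] * 3.71) %% 360 else numeric(0)
  synthetic_scene(pos, orient, rep("monomer", n), sim$params$field_um,
                  params = list(frame = frame_i, seed = sim$params$seed))
}

#' Synthetic pseudo-first-order coverage curve
#'
#' Samples `theta(t) = theta_inf * (1 - exp(-k t)) + N(0, noise_sigma)`,
#' clipped to \[0, 1\] — the standard fixture for kinetics-fitting tests.
#'
#' @param theta_inf saturation coverage in (0, 1].
#' @param k rate constant in s^-1.
#' @param noise_sigma Gaussian noise s.d.
#' @param n_points number of samples.
#' @param fps sampling rate (frames/s).
#' @param seed integer seed.
#' @return A [as_coverage_series()] object.
#' @export
synth_coverage_curve <- function(theta_inf, k, noise_sigma = 0,
                                 n_points = 600, fps = 1, seed = 1L) {
  stopifnot(theta_inf > 0, theta_inf <= 1, k > 0)
  t <- (seq_len(n_points) - 1) / fps
  with_seed(seed, {
    th <- theta_inf * (1 - exp(-k * t))
    if (noise_sigma > 0) th <- th + stats::rnorm(n_points, sd = noise_sigma)
    as_coverage_series(t, pmin(pmax(th, 0), 1),
                       series_id = sprintf("synth_k%.4g", k))
  })
}
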