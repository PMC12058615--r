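test_that("degenerate frames are handled per contract", {
  z <- scan_frame(matrix(0, 100, 100), 5)
  pf <- detect_particles(z, detection_params())
  expect_equal(nrow(pf$particles), 0)
  expect_equal(pf$coverage, 0)
  nanf <- scan_frame(matrix(1, 10, 10), 5)
  nanf$heights[3, 3] <- NaN
  # NaN slips past the constructor guard only by direct mutation
  expect_error(detect_particles(nanf, detection_params()), "NaN")
})

test_that("single rendered triangle is found at its true position", {
  sc <- synthetic_scene(cbind(430, 620), 25, "monomer", field_um = 1)
  fr <- render_frame(sc, pixel_size = 5, noise_sigma = 0.4, blur_nm = 3,
                     seed = 2)  # SNR 5
  pf <- detect_particles(flatten_lines(level_plane(fr), 1L),
                         detection_params(min_area_nm2 = 3000))
  expect_equal(nrow(pf$particles), 1)
  expect_lt(abs(pf$particles$x_nm - 430), 5)
  expect_lt(abs(pf$particles$y_nm - 620), 5)
  expect_equal(pf$particles$area_nm2, sqrt(3) / 4 * 120^2, tolerance = 0.25)
})

test_that("dense non-touching scene recovers >= 95 % of particles", {
  sc <- make_adsorbed_scene(80, field_um = 1.5, min_sep_nm = 140, seed = 13)
  fr <- render_frame(sc, pixel_size = 5, noise_sigma = 0.6, blur_nm = 3,
                     seed = 14)  # SNR ~ 3.3
  pf <- detect_particles(flatten_lines(level_plane(fr), 1L),
                         detection_params(min_area_nm2 = 3000))
  m <- match_positions(pf$particles[, c("x_nm", "y_nm")], sc$positions,
                       max_dist = 20)
  expect_gte(m$match_rate, 0.95)
})

test_that("classification bands and dimer fraction follow area ratios", {
  pf <- structure(list(
    particles = data.frame(x_nm = 1:3, y_nm = 1:3,
                           area_nm2 = c(1, 1, 2) * 6000,
                           mean_height_nm = 2, class = "unclassified",
                           component = 1:3),
    frame_area_um2 = 1, coverage = 0.1, timestamp = 0, threshold_nm = 1,
    dimer_fraction = NA_real_), class = "particle_field")
  out <- classify_particles(pf, reference_monomer_area = 6000)
  expect_equal(out$particles$class, c("monomer", "monomer", "dimer"))
  expect_equal(out$dimer_fraction, 1 / 3)
  # all equal areas: no dimers
  pf$particles$area_nm2 <- rep(6000, 3)
  expect_equal(classify_particles(pf, 6000)$dimer_fraction, 0)
  # empty field: missing value
  pf$particles <- pf$particles[0, ]
  expect_true(is.na(classify_particles(pf)$dimer_fraction))
})

test_that("planted touching dimers are recovered within 0.03", {
  sc <- make_adsorbed_scene(60, field_um = 2, min_sep_nm = 150,
                            dimer_fraction = 0.15, seed = 7)
  truth <- sc$params$true_dimer_fraction
  fr <- render_frame(sc, pixel_size = 5, noise_sigma = 0.4, blur_nm = 4,
                     seed = 8)
  pf <- classify_particles(detect_particles(
    flatten_lines(level_plane(fr), 1L),
    detection_params(min_area_nm2 = 3000)))
  expect_lt(abs(pf$dimer_fraction - truth), 0.03)
})

test_that("raising min_area never increases count or coverage", {
  d <- demo_frame(n = 25, seed = 17)
  fl <- flatten_lines(level_plane(d$frame), 1L)
  prev_n <- Inf; prev_cov <- Inf
  for (amin in c(2000, 4000, 7000, 13000)) {
    pf <- detect_particles(fl, detection_params(min_area_nm2 = amin,
                                                split_monolayer = FALSE))
    expect_lte(nrow(pf$particles), prev_n)
    expect_lte(pf$coverage, prev_cov)
    prev_n <- nrow(pf$particles); prev_cov <- pf$coverage
  }
})

test_that("detected count matches truth exactly at zero noise", {
  sc <- make_adsorbed_scene(30, field_um = 1.5, min_sep_nm = 170, seed = 23)
  fr <- render_frame(sc, pixel_size = 5, noise_sigma = 0, blur_nm = 0)
  pf <- detect_particles(fr, detection_params(threshold_mode = "fixed",
                                              threshold_nm = 1,
                                              min_area_nm2 = 3000))
  expect_equal(nrow(pf$particles), nrow(sc$positions))
})

test_that("monolayer components split into per-particle seeds", {
  sc <- make_lattice_scene(a = 110, field_um = 1, jitter_sigma = 3, seed = 3)
  fr <- render_frame(sc, pixel_size = 5, noise_sigma = 0.3, blur_nm = 3,
                     seed = 5)
  pf <- detect_particles(flatten_lines(level_plane(fr), 1L),
                         detection_params(min_area_nm2 = 3000,
                                          ref_area_nm2 = 6235))
  m <- match_positions(pf$particles[, c("x_nm", "y_nm")], sc$positions,
                       max_dist = 40)
  expect_gte(m$match_rate, 0.9)
  expect_equal(nrow(pf$particles), nrow(sc$positions), tolerance = 0.15)
})

test_that("parameter schedules validate coverage and select by time", {
  p1 <- detection_params(min_area_nm2 = 1000)
  p2 <- detection_params(min_area_nm2 = 9000)
  sch <- param_schedule(list(t_start = 0, t_end = 10, params = p1),
                        list(t_start = 10, t_end = 20, params = p2))
  expect_equal(params_at(sch, 3)$min_area_nm2, 1000)
  expect_equal(params_at(sch, 10)$min_area_nm2, 9000)
  expect_error(params_at(sch, 25), "gap")
  expect_error(param_schedule(
    list(t_start = 0, t_end = 10, params = p1),
    list(t_start = 5, t_end = 15, params = p2)), "overlap")
})

test_that("coverage is continuous across a schedule threshold switch", {
  sc <- make_adsorbed_scene(25, field_um = 1, min_sep_nm = 150, seed = 41)
  frames <- lapply(1:6, function(i)
    render_frame(sc, pixel_size = 5, timestamp = i - 1, frame_index = i - 1L))
  ser <- frame_series(frames, experiment_meta(6, 1, series_id = "cont"))
  mk <- function(thr) detection_params(threshold_mode = "fixed",
                                       threshold_nm = thr,
                                       min_area_nm2 = 3000)
  sch <- param_schedule(list(t_start = -Inf, t_end = 3, params = mk(0.8)),
                        list(t_start = 3, t_end = Inf, params = mk(1.2)))
  cov <- coverage_series(ser, sch, flatten_order = 0L)
  expect_lt(abs(cov$theta[3] - cov$theta[4]), 0.01)
})

test_that("identical frames give constant coverage", {
  d <- demo_frame(n = 15, seed = 51, noise = 0, blur = 0, scanline = 0)
  frames <- lapply(1:4, function(i) {
    f <- d$frame; f$timestamp <- i - 1; f$frame_index <- i - 1L; f })
  ser <- frame_series(frames, experiment_meta(6, 1))
  cov <- coverage_series(ser, flat_schedule(), flatten_order = 0L)
  expect_equal(length(unique(round(cov$theta, 10))), 1)
})
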