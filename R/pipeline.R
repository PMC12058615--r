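#' Parse a pipeline configuration
#'
#' Configurations are JSON documents with sections per stage. For
#' [run_analyze()]: `input` (series path), optional `sidecar`,
#' `flatten_order`, `window_deg`, `schedule` (list of
#' `{t_start, t_end, params}` with [detection_params()] fields), optional
#' `fft` (`{enabled, lattice_a}`), `out_dir`. For [run_simulate()]:
#' `sim` ([sim_params()] fields, `seed` mandatory), `render`
#' (`{pixel_size, noise_sigma, scanline_sigma, blur_nm, side_nm,
#' height_nm}`), plus the analyze keys.
#'
#' @param path JSON file path, or a list already in config shape.
#' @return The validated config list.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config not found: ", path)
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else path
  cfg
}

config_schedule <- function(cfg) {
  if (is.null(cfg$schedule))
    return(param_schedule(list(t_start = -Inf, t_end = Inf,
                               params = detection_params())))
  segs <- cfg$schedule
  if (is.data.frame(segs)) segs <- split(segs, seq_len(nrow(segs)))
  segs <- lapply(segs, function(s) {
    s <- as.list(s)
    pl <- if (!is.null(s$params)) as.list(s$params) else list()
    if (!is.null(pl[[1]]) && is.list(pl[[1]]) && is.null(names(pl)))
      pl <- pl[[1]]
    bad <- setdiff(names(pl), names(formals(detection_params)))
    if (length(bad))
      stop("config error: unknown detection parameter(s): ",
           paste(bad, collapse = ", "))
    list(t_start = if (is.null(s$t_start)) -Inf else s$t_start,
         t_end = if (is.null(s$t_end)) Inf else s$t_end,
         params = do.call(detection_params, pl))
  })
  param_schedule(segments = segs)
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(msg, con)
  invisible(msg)
}

#' Analyze a frame series end to end
#'
#' Reads a series, flattens every frame, runs scheduled detection, computes
#' the coverage trace, the per-frame Delaunay order parameter, the
#' pseudo-first-order kinetics fit with time-to-monolayer, and (optionally)
#' the FFT hexagonal-peak score of the final frame. Writes `coverage.csv`,
#' `order.csv`, `particles.csv`, `kinetics.json`, `fft.json`, `log.txt`
#' and a provenance block to the output directory. Outputs are
#' deterministic given identical inputs and config.
#'
#' @param config path to a JSON config or an equivalent list
#'   (see [read_config()]).
#' @return Invisibly, a list with the in-memory results
#'   (`coverage`, `order`, `kinetics`, `fft`, `out_dir`).
#' @export
run_analyze <- function(config) {
  cfg <- read_config(config)
  for (key in c("input", "out_dir"))
    if (is.null(cfg[[key]])) stop("config error: missing key '", key, "'")
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out, "log.txt"), "w")
  on.exit(close(logf))

  series <- read_series(cfg$input, cfg$sidecar)
  log_line(logf, "read %d frames from %s", length(series$frames), cfg$input)
  schedule <- config_schedule(cfg)
  flatten_order <- if (is.null(cfg$flatten_order)) 1L else cfg$flatten_order
  window_deg <- if (is.null(cfg$window_deg)) 5 else cfg$window_deg

  for (s in schedule$segments)
    log_line(logf, "schedule: [%g, %g) s -> threshold_mode=%s min_area=%g nm2",
             s$t_start, s$t_end, s$params$threshold_mode,
             s$params$min_area_nm2)

  cov <- coverage_series(series, schedule, flatten_order = flatten_order,
                         keep_fields = TRUE)
  fields <- attr(cov, "fields")
  ord <- order_series(series, schedule, window_deg = window_deg,
                      fields = fields)

  cov_df <- data.frame(t_s = cov$t, coverage = cov$theta,
                       n_particles = cov$n_particles,
                       dimer_fraction = cov$dimer_fraction)
  utils::write.csv(cov_df, file.path(out, "coverage.csv"), row.names = FALSE)
  utils::write.csv(ord, file.path(out, "order.csv"), row.names = FALSE)

  parts <- do.call(rbind, lapply(seq_along(fields), function(i) {
    p <- fields[[i]]$particles
    if (!nrow(p)) return(NULL)
    data.frame(frame_index = i - 1L, t_s = fields[[i]]$timestamp,
               x_nm = p$x_nm, y_nm = p$y_nm, area_nm2 = p$area_nm2,
               class = p$class)
  }))
  if (is.null(parts))
    parts <- data.frame(frame_index = integer(0), t_s = numeric(0),
                        x_nm = numeric(0), y_nm = numeric(0),
                        area_nm2 = numeric(0), class = character(0))
  utils::write.csv(parts, file.path(out, "particles.csv"), row.names = FALSE)

  kin <- tryCatch({
    fit <- fit_pseudo_first_order(cov)
    tml <- time_to_monolayer(cov, fit)
    list(series_id = series$meta$series_id,
         concentration_nM = series$meta$nominal_concentration,
         theta_inf = fit$theta_inf, k_per_s = fit$k,
         se_theta_inf = unname(fit$se["theta_inf"]),
         se_k = unname(fit$se["k"]), rss = fit$rss,
         n_points = fit$n_points,
         t_ml_s = tml$t_ml, t_ml_analytic_s = tml$t_ml_analytic,
         ml_fraction = tml$fraction, ml_reached = tml$reached)
  }, error = function(e) {
    log_line(logf, "kinetics fit skipped: %s", conditionMessage(e))
    list(series_id = series$meta$series_id, error = conditionMessage(e))
  })
  jsonlite::write_json(kin, file.path(out, "kinetics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  fft_res <- NULL
  fft_enabled <- is.null(cfg$fft$enabled) || isTRUE(cfg$fft$enabled)
  if (fft_enabled) {
    last <- series$frames[[length(series$frames)]]
    flat <- flatten_lines(level_plane(last), order = flatten_order)
    spec <- compute_spectrum(flat)
    a <- if (!is.null(cfg$fft$lattice_a)) cfg$fft$lattice_a else 110
    band <- hex_peak_radius(a) * c(0.7, 1.3)
    nyq <- 1 / (2 * last$pixel_size)
    band[2] <- min(band[2], nyq)
    score <- hexagonal_peak_score(spec, band)
    fft_res <- list(
      note = "peak-to-background ratio is a quantitative extension of the visual FFT comparison",
      frame_index = length(series$frames) - 1L,
      peak_radius_cyc_per_nm = score$peak_radius,
      expected_radius_cyc_per_nm = hex_peak_radius(a),
      peak_to_background = score$peak_to_background,
      n_peaks_found = score$n_peaks_found,
      peak_angles_deg = score$peak_angles)
    jsonlite::write_json(fft_res, file.path(out, "fft.json"),
                        auto_unbox = TRUE, digits = NA, na = "null")
  }

  prov <- list(
    package = "afmlattice",
    package_version = as.character(utils::packageVersion("afmlattice")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_md5 = if (is.character(config)) unname(tools::md5sum(config))
                 else NA_character_,
    n_frames = length(series$frames))
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  log_line(logf, "wrote results to %s", out)
  invisible(list(coverage = cov_df, order = ord, kinetics = kin,
                 fft = fft_res, out_dir = out))
}

#' Simulate, render and analyze a synthetic series
#'
#' Runs the adsorption simulator, renders each sampled frame, writes the
#' rendered series and per-frame ground truth, then runs [run_analyze()]
#' on the rendered data and emits a truth-vs-measured coverage table.
#'
#' @param config path to JSON config or list: `sim` ([sim_params()] fields,
#'   seed mandatory), `render` (renderer settings), `frame_stride` (render
#'   every k-th simulated frame, default 1), `out_dir`, plus analyze keys
#'   (`schedule`, `window_deg`, `flatten_order`, `fft`).
#' @return Invisibly, the [run_analyze()] result list, plus `truth`
#'   (data frame `t_s`, `theta_true`, `theta_measured`) and `sim`.
#' @export
run_simulate <- function(config) {
  cfg <- read_config(config)
  if (is.null(cfg$sim)) stop("config error: missing section 'sim'")
  if (is.null(cfg$out_dir)) stop("config error: missing key 'out_dir'")
  if (is.null(cfg$sim$seed))
    stop("config error: simulation seed is mandatory")
  bad <- setdiff(names(cfg$sim), names(formals(sim_params)))
  if (length(bad))
    stop("config error: unknown sim parameter(s): ",
         paste(bad, collapse = ", "))
  sp <- do.call(sim_params, cfg$sim)
  sim <- simulate_assembly(sp)

  rend <- as.list(cfg$render)
  stride <- if (is.null(cfg$frame_stride)) 1L else cfg$frame_stride
  pick <- seq(1, nrow(sim$summary), by = stride)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  frames <- lapply(seq_along(pick), function(i) {
    fi <- pick[i]
    do.call(render_frame, c(list(
      scene = sim_scene(sim, fi),
      timestamp = sim$summary$t_s[fi], frame_index = i - 1L,
      seed = child_seed(sp$seed, fi)), rend))
  })
  series <- frame_series(frames, experiment_meta(
    nominal_concentration = sp$target_concentration,
    frame_rate = sp$fps / stride,
    series_id = sprintf("sim_c%g_seed%d", sp$target_concentration, sp$seed)))
  series_dir <- file.path(out, "rendered")
  write_series(series, series_dir)
  utils::write.csv(sim$summary, file.path(out, "truth_summary.csv"),
                   row.names = FALSE)

  acfg <- cfg
  acfg$input <- series_dir
  acfg$sidecar <- file.path(series_dir, "sidecar.json")
  acfg$out_dir <- file.path(out, "analysis")
  res <- run_analyze(acfg)

  truth <- data.frame(t_s = sim$summary$t_s[pick],
                      theta_true = sim$summary$theta_true[pick],
                      theta_measured = res$coverage$coverage)
  utils::write.csv(truth, file.path(out, "truth_vs_measured.csv"),
                   row.names = FALSE)
  res$truth <- truth
  res$sim <- sim
  invisible(res)
}

#' Aggregate result bundles into a concentration-series report
#'
#' Combines [run_analyze()] output directories: per-series kinetics
#' (theta_inf, k, time to monolayer), final n(Theta60) computed as the
#' mean of five values from the last 50 s, the pairwise extra-sum-of-squares
#' F-test matrix between the coverage curves, and a one-way ANOVA on the
#' final order-parameter values. Writes `summary.csv` and `report.json`.
#'
#' @param bundle_dirs character vector of [run_analyze()] output dirs.
#' @param out_dir where to write the report (default: first bundle's parent).
#' @param final_window_s,final_n window and count for the final-order
#'   sampling (defaults 50 s, 5 values).
#' @return Invisibly, a list with `summary` (data frame), `anova`,
#'   `ftest`.
#' @export
run_report <- function(bundle_dirs, out_dir = NULL, final_window_s = 50,
                       final_n = 5) {
  if (!length(bundle_dirs)) stop("need at least one bundle")
  if (is.null(out_dir)) out_dir <- dirname(bundle_dirs[[1]])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundles <- lapply(bundle_dirs, function(b) {
    for (f in c("coverage.csv", "order.csv", "kinetics.json"))
      if (!file.exists(file.path(b, f)))
        stop("bundle ", b, " is missing ", f)
    list(dir = b,
         coverage = utils::read.csv(file.path(b, "coverage.csv")),
         order = utils::read.csv(file.path(b, "order.csv")),
         kinetics = jsonlite::read_json(file.path(b, "kinetics.json"),
                                        simplifyVector = TRUE))
  })
  finals <- lapply(bundles, function(b)
    select_final_orders(b$order$t_s, b$order$n_theta60_per_um2,
                        window_s = final_window_s, n_values = final_n))
  summary_df <- do.call(rbind, lapply(seq_along(bundles), function(i) {
    k <- bundles[[i]]$kinetics
    data.frame(
      series_id = if (!is.null(k$series_id)) k$series_id else basename(bundle_dirs[i]),
      concentration_nM = if (!is.null(k$concentration_nM)) k$concentration_nM else NA,
      theta_inf = if (!is.null(k$theta_inf)) k$theta_inf else NA,
      k_per_s = if (!is.null(k$k_per_s)) k$k_per_s else NA,
      t_ml_s = if (!is.null(k$t_ml_s)) k$t_ml_s else NA,
      final_n_theta60 = mean(finals[[i]]))
  }))
  names(finals) <- make.unique(as.character(summary_df$series_id))

  anova_res <- if (length(bundles) >= 2)
    final_order_anova(finals) else NULL
  ftest_res <- if (length(bundles) >= 2) {
    sl <- lapply(bundles, function(b)
      as_coverage_series(b$coverage$t_s, pmin(pmax(b$coverage$coverage, 0), 1),
                         series_id = b$kinetics$series_id))
    tryCatch(compare_datasets_ftest(sl), error = function(e) NULL)
  } else NULL

  utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  rep <- list(summary = summary_df,
              anova = if (!is.null(anova_res))
                anova_res[c("F", "df1", "df2", "p")] else NULL,
              pairwise_ftest = if (!is.null(ftest_res)) ftest_res$pairwise
                               else NULL)
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(list(summary = summary_df, anova = anova_res,
                 ftest = ftest_res))
}
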