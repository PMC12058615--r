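# Shared fixture builders: everything is generated in code at test time.

# Small rendered frame with a known scene, moderate noise (SNR ~ 5).
demo_frame <- function(n = 20, field_um = 1, seed = 1, noise = 0.4,
                       blur = 3, scanline = 0.3) {
  sc <- make_adsorbed_scene(n, field_um = field_um, min_sep_nm = 160,
                            seed = seed)
  fr <- render_frame(sc, pixel_size = 5, noise_sigma = noise,
                     scanline_sigma = scanline, blur_nm = blur,
                     seed = seed + 1000)
  list(scene = sc, frame = fr)
}

# Whole-series schedule with one parameter set.
flat_schedule <- function(params = detection_params(min_area_nm2 = 3000)) {
  param_schedule(list(t_start = -Inf, t_end = Inf, params = params))
}

# Short rendered series from the adsorption simulator.
demo_series <- function(duration = 12, seed = 5, conc = 6) {
  sim <- simulate_assembly(sim_params(
    target_concentration = conc, injection_lag_tau = 5,
    attempt_rate_per_nM = 1.5, duration_s = duration, fps = 1, seed = seed))
  frames <- lapply(seq_len(duration), function(i)
    render_frame(sim_scene(sim, i), pixel_size = 5, noise_sigma = 0.3,
                 blur_nm = 3, timestamp = sim$summary$t_s[i],
                 frame_index = i - 1L, seed = seed * 100 + i))
  list(sim = sim,
       series = frame_series(frames, experiment_meta(conc, 1,
                                                     series_id = "demo")))
}
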