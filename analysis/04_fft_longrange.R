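#!/usr/bin/env Rscript
# Long-range order from the Fourier magnitude spectrum: render overview
# fields at increasing positional disorder, locate the six first-order
# correlation peaks of the hexagonal lattice, and tabulate the
# peak-to-background score (our quantitative proxy for the visual
# sharp-peaks-vs-diffuse-background comparison of AFM image FFTs).

library(afmlattice)
dir.create("results", showWarnings = FALSE)

a <- 110  # nm lattice constant; first-order peaks at 2/(sqrt(3) a)
rows <- lapply(c(0, 5, 10, 20), function(sj) {
  sc <- make_lattice_scene(a = a, field_um = 2, jitter_sigma = sj,
                           grain_count = if (sj > 0) 3 else 1, seed = 900 + sj)
  fr <- render_frame(sc, pixel_size = 5, noise_sigma = 0.3, seed = 901 + sj)
  hs <- hexagonal_peak_score(compute_spectrum(fr),
                             hex_peak_radius(a) * c(0.7, 1.3))
  data.frame(jitter_sigma_nm = sj,
             n_peaks = hs$n_peaks_found,
             peak_radius_cyc_nm = hs$peak_radius,
             expected_radius_cyc_nm = hex_peak_radius(a),
             peak_to_background = hs$peak_to_background)
})
tab <- do.call(rbind, rows)
write.csv(tab, file.path("results", "fft_scores.csv"), row.names = FALSE)
cat("hexagonal peak scores on 2 um rendered fields:\n")
print(tab, row.names = FALSE, digits = 4)
cat(sprintf(
  "\nperfect lattice: %d peaks at %.5f cycles/nm (reciprocal-lattice value %.5f)\n",
  tab$n_peaks[1], tab$peak_radius_cyc_nm[1], hex_peak_radius(a)))
cat("the score decreases with disorder; grains broaden peaks into arcs\n")
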