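# Small synthetic field factories shared across tests. Fields are kept at or
# below 64x64 px so that the brute-force oracles stay fast.

small_config <- function(seed, n_vessels = 1L, lambda = 10, sigma = 0,
                         leaky_fraction = 1, size = 64L,
                         min_separation_um = 24) {
  simulation_config(
    image_height_px = size, image_width_px = size, pixel_size_um = 1,
    n_vessels = n_vessels, vessel_length_um = 14, lumen_radius_um = 2.5,
    nucleus_radius_um = 1.5, nucleus_spacing_um = 2,
    intravascular_intensity = 150, leaky_fraction = leaky_fraction,
    halo_amplitude = 200, decay_length_um = lambda,
    background_sigma = sigma, min_separation_um = min_separation_um,
    border_margin_um = 10, seed = seed)
}
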