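# Shared fixture builders.  All scenes are generated in code at test time;
# 4 um/px keeps single-bead fields at 256 px.

single_bead_scene <- function(diameter_um = 650, pixel_size_um = 4,
                              noise_sd = 0.02, seed = 1, side = 256,
                              modality = "brightfield", ...) {
  spec <- scene_spec(side, side, pixel_size_um, modality,
                     noise_sd = noise_sd, seed = seed)
  ctr <- (side - 1) / 2
  bead <- bead_spec(ctr, ctr, diameter_um, ...)
  if (modality == "brightfield") render_brightfield_scene(spec, bead)
  else render_fluorescence_scene(spec, bead)
}

overgrowth_arc <- function(coverage, start_deg = 30, band_width_um = 40,
                           contrast = 0.6) {
  if (coverage <= 0) return(NULL)
  if (coverage >= 1 - 1e-9)
    return(data.frame(start_deg = 0, end_deg = 360,
                      band_width_um = band_width_um, contrast = contrast))
  data.frame(start_deg = start_deg %% 360,
             end_deg = (start_deg + 360 * coverage) %% 360,
             band_width_um = band_width_um, contrast = contrast)
}
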