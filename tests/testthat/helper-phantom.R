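# Shared desk-scale phantom builders: 24-channel protocol (3 lights x
# 480-620 nm), 200 x 150 px frame, one centered 3 x 1.5 mm flavin-like
# stain (60 x 30 px at 0.05 mm/px).

small_protocol <- function(frame_width = 200, frame_height = 150,
                           filter_min = 480, filter_max = 620) {
  make_protocol(default_lights(), filter_min, filter_max, 20,
                frame_width = frame_width, frame_height = frame_height)
}

fig2_pair <- function(noise_sd = 0, seed = 0L, concentration = 1,
                      protocol = small_protocol()) {
  render_pair(default_scene(protocol, noise_sd = noise_sd, seed = seed,
                            concentration = concentration), protocol)
}

# analysis crop around the planted stain (stain occupies cols 70-129,
# rows 60-89 of the 200 x 150 frame)
stain_crop_region <- function() px_region(50, 45, 100, 60)

crop_truth <- function(pair, region = stain_crop_region()) {
  stain_mask(pair$truth$mask[region$y0 + seq_len(region$height),
                             region$x0 + seq_len(region$width)],
             source = "planted (crop)")
}

# background and stain intensity levels of the green/500 nm channel,
# measured from a noise-free rendering (used to place thresholds and to set
# the signal-to-noise gap of stochastic suites)
green500_levels <- function() {
  pair <- fig2_pair(noise_sd = 0)
  fr <- select_channel(pair$dirty, "green", 500)$frame
  list(background = fr[1, 1], stain = fr[75, 100],
       gap = fr[75, 100] - fr[1, 1])
}
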