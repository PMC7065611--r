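test_that("protocol grids enumerate every light x filter pair", {
  cases <- list(
    list(lights = default_lights(), min = 420, max = 720, step = 20,
         expect = 48),
    list(lights = default_lights()[2], min = 500, max = 500, step = 20,
         expect = 1),
    list(lights = default_lights()[1:2], min = 420, max = 460, step = 20,
         expect = 6)
  )
  for (cs in cases) {
    p <- make_protocol(cs$lights, cs$min, cs$max, cs$step)
    expect_equal(nrow(p$channels), cs$expect)
    expect_equal(nrow(p$channels), length(cs$lights) * length(p$filters))
    expect_equal(anyDuplicated(p$channels[, c("light", "i_rel", "filter_nm")]),
                 0L)
  }
  expect_equal(make_protocol(default_lights())$frame_width, 1393L)
  expect_equal(make_protocol(default_lights())$frame_height, 1040L)
  expect_error(make_protocol(default_lights(), increment = 0),
               "invalid protocol")
  expect_error(make_protocol(default_lights(), 720, 420), "invalid protocol")
})

test_that("light and filter constructors enforce physical ranges", {
  expect_error(excitation_light("green", 525, 256), "relative_intensity")
  expect_error(excitation_light("green", 300, 50), "center_wavelength")
  expect_error(excitation_light("ultraviolet", 365, 50))
  expect_error(bandpass_filter(500, 0), "passband_fwhm")
  expect_error(fluorophore(excitation_peak = 550, emission_peak = 500),
               "Stokes")
})

test_that("channel response: peak-on-peak positive, off-band zero, linear in drive", {
  fl <- fluorophore()
  f500 <- bandpass_filter(500)
  matched <- excitation_light("blue", 450, 255)
  expect_gt(channel_response(fl, matched, f500), 0)
  # 720 nm filter is > 5 combined emission widths from the 500 nm peak
  expect_identical(channel_response(fl, matched, bandpass_filter(720)), 0)
  # excitation > 5 widths away is also dark
  narrow <- fluorophore(excitation_peak = 450, excitation_width = 10,
                        emission_peak = 500)
  expect_identical(
    channel_response(narrow, excitation_light("red", 625, 255), f500), 0)
  # doubling the drive level doubles the contribution
  l50 <- excitation_light("green", 525, 50)
  l100 <- excitation_light("green", 525, 100)
  expect_equal(channel_response(fl, l100, f500),
               2 * channel_response(fl, l50, f500))
  # and quantum_scale is linear too
  fl2 <- fluorophore(quantum_scale = 60)
  expect_equal(channel_response(fl2, l50, f500),
               2 * channel_response(fl, l50, f500))
})

test_that("noise-free rendering: empty-scene identity and exact planted geometry", {
  p <- small_protocol()
  empty <- scene_spec(noise_sd = 0)
  pair0 <- render_pair(empty, p)
  expect_identical(pair0$dirty$frames, pair0$clean$frames)
  expect_false(any(pair0$truth$mask))

  pair <- fig2_pair(noise_sd = 0)
  # 3 x 1.5 mm at 0.05 mm/px -> 60 x 30 px rectangle
  s <- mask_summary(pair$truth, pixel_scale = 0.05)
  expect_equal(s$pixel_count, 60 * 30)
  expect_equal(s$area_mm2, 4.5)
  expect_equal(s$bbox$width, 60L)
  expect_equal(s$bbox$height, 30L)
  # dirty - clean differs exactly on the planted mask, in >= 1 channel
  diffs <- Reduce(`|`, Map(function(d, c_) abs(d - c_) > 0,
                           pair$dirty$frames, pair$clean$frames))
  expect_identical(diffs, pair$truth$mask)
})

test_that("rendering is deterministic under a fixed seed and clipped to [0, 1]", {
  a <- fig2_pair(noise_sd = 0.1, seed = 7L)
  b <- fig2_pair(noise_sd = 0.1, seed = 7L)
  expect_identical(a$dirty$frames, b$dirty$frames)
  expect_identical(a$clean$frames, b$clean$frames)
  c_ <- fig2_pair(noise_sd = 0.1, seed = 8L)
  expect_false(identical(a$dirty$frames, c_$dirty$frames))
  rng <- range(unlist(a$dirty$frames))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
  # noise at the ceiling still clips
  loud <- scene_spec(background_reflectance = 0.9, noise_sd = 5, seed = 1L)
  expect_lte(max(unlist(render_pair(loud, small_protocol())$dirty$frames)), 1)
})

test_that("increasing stain concentration never darkens any pixel", {
  p <- small_protocol()
  lo <- fig2_pair(noise_sd = 0, concentration = 0.5, protocol = p)
  hi <- fig2_pair(noise_sd = 0, concentration = 2, protocol = p)
  for (i in seq_along(lo$dirty$frames)) {
    expect_true(all(hi$dirty$frames[[i]] >= lo$dirty$frames[[i]]))
  }
})

test_that("overexposure: full drive with light on filter saturates, drive 50 does not", {
  # green LED (525 nm) with the 520 nm filter: closer than one filter FWHM
  sat_lights <- list(excitation_light("green", 525, 255))
  p255 <- make_protocol(sat_lights, 520, 520, 20,
                        frame_width = 40, frame_height = 30)
  scene <- scene_spec(noise_sd = 0)
  frame255 <- render_pair(scene, p255)$clean$frames[[1]]
  expect_true(any(frame255 == 1))
  p50 <- make_protocol(list(excitation_light("green", 525, 50)), 520, 520, 20,
                       frame_width = 40, frame_height = 30)
  frame50 <- render_pair(scene, p50)$clean$frames[[1]]
  expect_true(all(frame50 < 1))
})

test_that("stains outside the scene bounds are a geometry error", {
  p <- small_protocol()
  bad <- scene_spec(stains = list(
    stain_region("rectangle", center = c(9.5, 3), extent = c(3, 1.5))))
  expect_error(render_pair(bad, p), "geometry error")
})

test_that("a scene/protocol YAML config round-trips into the same rendering", {
  cfg_path <- system.file("extdata", "example_scene.yaml",
                          package = "surfstain")
  sc <- read_scene_config(cfg_path)
  expect_equal(nrow(sc$protocol$channels), 24)
  from_yaml <- render_pair(sc$scene, sc$protocol)
  direct <- render_pair(default_scene(small_protocol(),
                                      noise_sd = 0.02, seed = 0L),
                        small_protocol())
  expect_identical(from_yaml$dirty$frames, direct$dirty$frames)
})
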