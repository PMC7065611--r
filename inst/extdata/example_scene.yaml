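# One invisible flavin-like stain on a varnished surface, desk-scale frame.
seed: 0
pixel_scale_mm: 0.05
background_reflectance: 0.2
noise_sd: 0.02
leakage_gain: 1.2
frame:
  width: 200
  height: 150
lights:
  - {name: red, center_nm: 625, i_rel: 255}
  - {name: green, center_nm: 525, i_rel: 50}
  - {name: blue, center_nm: 460, i_rel: 50}
filters:
  min_nm: 480
  max_nm: 620
  increment_nm: 20
  passband_fwhm: 10
stains:
  - shape: rectangle
    center_mm: [5.0, 3.75]
    extent_mm: [3.0, 1.5]
    concentration: 1
    fluorophore:
      name: flavin-like
      excitation_peak: 450
      excitation_width: 60
      emission_peak: 500
      emission_width: 25
      quantum_scale: 30
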