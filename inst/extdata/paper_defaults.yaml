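geometry:
  pixel_pitch: 0.2152
  z_step: 0.4
  planes_autophagy: 5
  planes_mitophagy: 11
preprocess:
  iterations: 10
  flatfield_smooth_sd: 20.0
  psf:
    green:
      wavelength_em: 520.0
      numerical_aperture: 1.2
      refractive_index: 1.33
    red:
      wavelength_em: 600.0
      numerical_aperture: 1.2
      refractive_index: 1.33
    lysotracker:
      wavelength_em: 690.0
      numerical_aperture: 1.2
      refractive_index: 1.33
dsred:
  dog_fg:
  - 20.0
  - 1.0
  dog_bg:
  - 20.0
  - 7.0
  dog_threshold: 400.0
  tophat_radius: 25.0
  tophat_threshold: 1200.0
  split_min_size: 500.0
  split_overlap: 0.1
  dog2_fg:
  - 11.0
  - 1.0
  dog2_bg:
  - 25.0
  - 6.0
  dog2_threshold: 1000.0
  dog2_size:
  - 200.0
  - 2000.0
green:
  dog_fg:
  - 100.0
  - 1.0
  dog_bg:
  - 100.0
  - 5.0
  dog_threshold: 1000.0
  log_size: 20.0
  log_sd: 1.0
  log_threshold: -2000.0
  min_component: 10.0
ratio:
  blur:
  - 5.0
  - 2.0
  eps: 1.0
autolyso:
  tophat_radius: 15.0
  threshold: 1.5
  neighborhood_radius: 7.0
  brighter_factor: 1.5
  min_volume: 100.0
autophagosome:
  butterworth_cutoff: 10.0
  butterworth_order: 5.0
  threshold: 150.0
  min_object: 20.0
  opening_radius: 1.0
  proportion_ratio: 1.01
  proportion_diff: 20.0
  hole_max: 10000.0
  restore_opening_radius: 5.0
  hough:
    radii:
    - 3.0
    - 30.0
    erosion_radius: 2.0
    mad_min: 20.0
    red_q90_max: 300.0
    sensitivity: 0.25
  size_range:
  - 50.0
  - 10000.0
  sphericity1_min: 1.0
  sphericity2_min: 1.5
classification:
  mean_red_min: 300.0
  eccentricity_max: 0.9
mitophagy:
  dog_fg:
  - 50.0
  - 1.0
  dog_bg:
  - 50.0
  - 2.0
  threshold: 12.0
  ratio_max: 0.6
  limit_fg:
  - 50.0
  - 1.0
  limit_bg:
  - 50.0
  - 5.0
  limit_threshold: 50.0
lysotracker:
  dog_fg:
  - 100.0
  - 1.0
  dog_bg:
  - 100.0
  - 5.0
  dog_threshold: 2000.0
  log_size: 20.0
  log_sd: 1.0
  log_threshold: -2000.0
  min_component: 10.0
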