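# Example configuration: a segmental airway against an enhanced
# pulmonary artery (pulmonary-arterial phase), soft-kernel blur, 20 HU
# noise. Render with:
#   bronchoquant simulate --config phantom_example.yaml --out slice
phantom:
  lumen_radius_mm: 2.5
  wall_thickness_mm: 1.0
  vessel_radius_mm: 6.0
  vessel_hu: 725          # phase_preset("PA")
  vessel_gap_mm: 0.0
  vessel_angle_deg: 0.0
  psf_sigma_mm: 0.6
  noise_sd_hu: 20
  image_size_mm: 30
  spacing_mm: 0.5
  seed: 42
ibm:
  psf_sigma_mm: 0.65      # effective blur: PSF plus pixel sampling
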