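geometry:
  ring_diameter_cm: 1.7
  bone_center_cm:
  - 0.0
  - 0.3
  bone_size_cm:
  - 0.5
  - 0.3
  artery_center_cm:
  - 0.4
  - 0.45
  artery_radius_cm: 0.08
  skin_thickness_cm:
    epidermis: 0.01
    papillary_dermis: 0.02
    upper_blood_net_dermis: 0.008
    reticular_dermis: 0.08
    deep_blood_net_dermis: 0.03
  length_cm: 4.0
  pd_size_cm:
  - 0.3
  - 0.3
  led_radius_cm: 0.15
physiology:
  spo2: 0.98
  systolic:
    artery_radius_cm: 0.08
    capillary_multiplier: 1.0
  diastolic:
    artery_radius_cm: 0.092
    capillary_multiplier: 1.5
source:
  wavelength_nm: 660.0
  profile: lambertian
detector:
  theta_deg: 25.0
boundary:
  rho: 0.0
sweep:
  theta_deg:
  - 25.0
  - 30.0
  - 35.0
  - 40.0
  - 45.0
  - 50.0
  - 55.0
  - 60.0
  - 65.0
  - 70.0
  - 75.0
  - 80.0
  - 85.0
  - 90.0
  - 95.0
  wavelengths_nm:
  - 660.0
  - 940.0
  spo2:
  - 0.7
  - 0.8
  - 0.9
  - 1.0
  rho:
  - 0.0
  - 1.0
  n_photons: 100000.0
  n_repeats: 1.0
n_photons: 100000.0
seed: 1.0
spectra_path: ~
out_dir: '.'
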