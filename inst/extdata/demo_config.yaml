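# Demo configuration for crosskymo::runPipeline().
# Any key omitted here falls back to defaultRunConfig().
seed: 1

dynamics:
  n_microtubules: 10
  duration_s: 600
  seed_length_um: 2
  conditions:
    control:
      v_growth_um_per_min: 2
      v_shrink_um_per_min: 30
      f_cat_per_s: 0.005
      f_res_per_s: 0.02
    crosslinker:
      v_growth_um_per_min: 1.6
      v_shrink_um_per_min: 25
      f_cat_per_s: 0.008
      f_res_per_s: 0.03

binder:
  k_on_per_um_per_s: 0.05
  k_off_gdp_per_s: 1.07
  k_off_seed_per_s: 0.26
  diffusion_um2_per_s: 0.05
  lattice_um: 10
  seed_length_um: 2
  duration_s: 200
  frame_interval_s: 0.1

frap:
  n_traces: 12
  plateau: 0.8
  n_prebleach: 55
  n_postbleach: 120
  frame_interval_s: 0.2
  noise_sigma: 0.05
  conditions:
    gdp: 1.07
    gmpcpp: 0.26

events:
  n_per_class: 10
  duration_s: 24
  frame_interval_s: 2

optics:
  pixel_size_um: 0.1
  frame_interval_s: 2
  psf_sigma_px: 1.3
  photons_per_fluor: 200
  background_level: 100
  noise_model: poisson
  gaussian_sigma: 10
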