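n_ica: 20.0
n_ica_ranked: 10.0
kurtosis_range:
- 1.0
- 10.0
gof_threshold_mag: 0.8
gof_threshold_grad: 0.6
gof_override: 0.95
peak_band:
- 20.0
- 90.0
min_peaks: 300.0
peak_grid:
- 8.0
- 7.0
- 6.0
- 5.0
- 4.0
- 3.0
- 2.5
- 2.0
music_window:
- -0.02
- 0.03
refractory: 0.5
csc_band:
- 2.0
- 90.0
n_atoms_per_run: 3.0
atom_len: 0.5
lambda_reg: 0.1
epoch_len: 1.0
mad_start: 7.0
mad_floor: 1.5
mad_grid:
- 7.0
- 6.0
- 5.0
- 4.0
- 3.0
- 2.5
- 2.0
- 1.5
min_events: 15.0
events_cap: 20.0
n_runs: 4.0
binarize_frac: 0.5
smooth_mm: 10.0
resection_margin_mm: 3.0
lambda2: 0.111111111111
csc_n_iter: 40.0
csc_tol: 1.0e-05
exclude_atoms: []
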