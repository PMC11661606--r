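'n': 400
m: 1000
block_size: 20
maf_range:
- 0.1
- 0.5
spacing_bp: 5000
n_polar: 10
n_lateral: 9
k_latent: 12
n_causal: 8
h2_target: 0.6
latent_sd: 3.0
n_random: 8
n_extreme: 8
k_syndromes: 3
syndrome_shift: 4.0
n_per_syndrome: 30
n_syndrome_controls: 40
ae_latent: 6
ae_hidden:
- 32
- 16
ae_epochs: 60
base_alpha: 5.0e-08
clump_bp: 250000.0
ld_bp: 1000000.0
merge_bp: 1.0e+07
r2: 0.01
ld_window_bp: 1000000.0
distinctness_perm: 199
seed: 1
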