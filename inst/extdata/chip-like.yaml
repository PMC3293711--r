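# ChIP-on-chip-like study conditions: binding sites cover little of the
# genome, so the enriched component is small and the control/promoter
# log-ratio densities largely overlap. Differs from the MeDIP-like preset
# only in the enriched fraction and the number of planted tiling sites.
n_arrays: 8
n_tiling_probes: 8000
n_control_probes: 2000
n_promoter_probes: 30000
probe_spacing: 100
probe_length: 50
enriched_fraction: 0.02
enrichment_shift: 2.0
site_weight: 1.0
occupancy: [2.0, 1.0]
mean_fragment_length: 600
site_halfwidth: 500
background_mean: 10.0
background_sd: 1.0
background_floor_drop: 2.5
ip_floor_drop: 2.0
nonspecific_retention: 0.25
noise_sd: 0.25
dye_trend_coeffs: [0.0, 0.1, -0.03]
array_trend_sd: 0.4
array_scale_sd: 0.15
array_offset_sd: 0.15
array_ip_sd: 0.15
n_planted_sites: 5
seed: 1
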