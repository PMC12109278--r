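# Early-stage in-vivo replication intermediate: 2 kb parental circle,
# 25% replicated, negative superhelical stress confined to the
# unreplicated region and right-handed precatenanes in the braid.
n_bp: 2000
n_rep: 509
q_unrep: -12.0
q_wrap: 0.0
q_rep: 2.0
precatenane_Ca: 2.0
braid_writhe: 0.0
n_plectoneme_branches: 1
seed: 1
helical_repeat_h: 10.5
rise_per_bp: 0.34
duplex_radius: 1.0
superhelix_radius: 4.5
braid_radius: 4.0
unrep_twist_fraction: 0.3
fork_gap_nm: 12.0
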