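name: TSOCD_BIVAR
h2_liability: 0.58
prevalence_K: 0.008
partition_shares:
  all: 1.0
n_causal_per_partition:
  all: 500
rg: 0.41
h2_liability2: 0.37
prevalence_K2: 0.025
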