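name: TS_GENIC
h2_liability: 0.58
prevalence_K: 0.008
partition_shares:
  genic: 0.53
  intergenic: 0.47
n_causal_per_partition:
  genic: 250
  intergenic: 250
rg: ~
h2_liability2: ~
prevalence_K2: ~
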