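name: OCD_GLOBAL
h2_liability: 0.37
prevalence_K: 0.025
partition_shares:
  all: 1.0
n_causal_per_partition:
  all: 500
rg: ~
h2_liability2: ~
prevalence_K2: ~
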