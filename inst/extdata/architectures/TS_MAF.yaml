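name: TS_MAF
h2_liability: 0.58
prevalence_K: 0.008
partition_shares:
  maf_bin1: 0.21
  maf_bin2: 0.030384615384615
  maf_bin3: 0.182307692307692
  maf_bin4: 0.202564102564103
  maf_bin5: 0.263333333333333
  maf_bin6: 0.111410256410256
n_causal_per_partition:
  maf_bin1: 60
  maf_bin2: 60
  maf_bin3: 60
  maf_bin4: 60
  maf_bin5: 60
  maf_bin6: 60
rg: ~
h2_liability2: ~
prevalence_K2: ~
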