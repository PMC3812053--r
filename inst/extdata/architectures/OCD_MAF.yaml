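name: OCD_MAF
h2_liability: 0.37
prevalence_K: 0.025
partition_shares:
  maf_bin1: 0.0
  maf_bin2: 0.111111111111111
  maf_bin3: 0.232323232323232
  maf_bin4: 0.03030303030303
  maf_bin5: 0.313131313131313
  maf_bin6: 0.313131313131313
n_causal_per_partition:
  maf_bin1: 0
  maf_bin2: 60
  maf_bin3: 60
  maf_bin4: 60
  maf_bin5: 60
  maf_bin6: 60
rg: ~
h2_liability2: ~
prevalence_K2: ~
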