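# Example reduced-scale study configuration for inst/cli/testmat.R.
# Full-scale values in the study design: N 5000, replications 10,
# burn_cap determined by the Geweke criterion (14500-80000).
seed: 1
N: 200
replications: 2
max_items: 54
P: 3
rho: 0.80
info_mode: sum
shrinkage: closed_form
burn_min: 1000
burn_cap: 2500
retain: 500
conditions:
  - size: 3
    sigma2: 0.5
    model: MTIRT
    algorithm: MAT
  - size: 3
    sigma2: 0.5
    model: MTIRT
    algorithm: RAN
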