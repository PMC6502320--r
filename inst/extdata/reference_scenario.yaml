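true_N: 11528
age_mean: 82.22
age_sd: 6.53
age_bounds:
- 40.0
- 110.0
female_fraction: 0.721
pA:
  F:
  - 0.1535
  - 0.6922
  - 0.6922
  M:
  - 0.1075
  - 0.5991
  - 0.5991
pB:
  F:
  - 0.2225
  - 0.221
  - 0.221
  M:
  - 0.2334
  - 0.2317
  - 0.2317
delta: 0.0
dup_rate: 0.0
seed: 42
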