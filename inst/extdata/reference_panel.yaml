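# Laboratory reference values with 10% border zones.
abeta42:
  cutoff: 580.0
  direction: low
  border_fraction: 0.10
abeta42_40_ratio:
  cutoff: 0.068
  direction: low
  border_fraction: 0.10
tau:
  cutoff: 250.0
  direction: high
  border_fraction: 0.10
ptau181:
  cutoff: 37.0
  direction: high
  border_fraction: 0.10
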