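# Example experiment configuration: disparity sweep locating the
# integration-vs-segregation decision boundary on a reduced grid.
preset: decision
params:
  N: 36
protocol:
  disparities: [20, 40, 60, 80, 100, 120, 140, 160]
  duration: 15
  burn_in: 15
seed: 42
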