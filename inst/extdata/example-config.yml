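# Example run configuration: a deliberately small domain and high drive
# frequencies so the run completes in seconds. Remove the overrides to fall
# back to the 50 x 20 default domain and its knee-straddling frequency grid.
grid:
  nx: 10
  ny: 6
model:
  kappa: 0.002
  amplitude: 0.01
sweep:
  frequencies: [0.05, 0.1, 0.2]
  transient_periods: 3
  measure_periods: 2
seed: 42
output: example-sweep.csv
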