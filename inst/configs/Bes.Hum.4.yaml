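# Bes.Hum.4: four 50 uL drops of 0.6% w/v suspension, ten minutes apart (human)
schema_version: 1
mode: simulate
seed: 1
drug:
  builtin: besifloxacin
formulation:
  builtin: besivance
physiology:
  species: human
protocol:
  times: [0, 0.1666666667, 0.3333333333, 0.5]
  volume: 50
  strength: 6
solver:
  t_end: 24
  n_out: 241
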