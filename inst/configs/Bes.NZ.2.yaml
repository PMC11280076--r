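# Bes.NZ.2: single 50 uL drop of 0.6% w/v suspension (NZ_rabbit)
schema_version: 1
mode: simulate
seed: 1
drug:
  builtin: besifloxacin
formulation:
  builtin: besivance
physiology:
  species: NZ_rabbit
protocol:
  times: [0]
  volume: 50
  strength: 6
solver:
  t_end: 24
  n_out: 241
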