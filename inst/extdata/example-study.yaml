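# Small worked example for `modexp simulate` / read_sim_config().
# NOTE: quote the "n" key -- bare n is a YAML 1.1 boolean (the reader also
# accepts the unquoted form and repairs it).
"n": 100
p: 5
law: uniform
model: C1
replications: 50
seed: 1
designs:
  cre:
    name: cre
  rem:
    name: rem
    acceptance: 0.2
  mode:
    name: mode
    kernel: energy
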