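# Small example run: isolated random-search bots, 10 replicates.
# All omitted keys fall back to the game's default constants
# (6/27/115 items, 188-attempt budget, 15 epochs, 15 points per
# innovation, value floor 50).
tree:
  generate:
    n_base: 6
    n_intermediate: 27
    n_logs: 115
structure:
  variant: isolated
  group_size: 1
experiment:
  n_replicates: 10
  seed: 42
output:
  dir: totemsim_output
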