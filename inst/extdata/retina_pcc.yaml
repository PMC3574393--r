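# Default P&CC experiment on the L-AND-R retina task (full study scale).
# The object sets below transcribe the packaged defaults explicitly so
# they can be edited; delete the block to use the built-ins.
task: retina_and
treatment: PCC_length
p_cost: 0.25
pop_size: 1000
generations: 25000
mutation:
  add: 0.20
  remove: 0.20
  threshold: 0.041666667
  weight: 2.0
weight_mode: integer
seed: 1
objects:
  left:  ['1110', '1101', '1011', '0111', '1111', '1100', '1010', '1001']
  right: ['1110', '1101', '1011', '0111', '1111', '0011', '0101', '1001']
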