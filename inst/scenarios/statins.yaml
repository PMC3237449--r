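name: statin-like inhibition of the mevalonate entry steps (balanced variant)
kind: total_mass
variant: balanced
times: [120]
conditions:
  "10% thiolase/synthase": {enzyme: X171, fraction: 0.10}
  "1% thiolase/synthase": {enzyme: X171, fraction: 0.01}
  "10% HMG reductase": {enzyme: X172, fraction: 0.10}
  "1% HMG reductase": {enzyme: X172, fraction: 0.01}
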