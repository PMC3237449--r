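name: total-mass fold-change tables (balanced variant)
kind: total_mass
variant: balanced
times: [60, 120]
conditions:
  "1% SPT": {enzyme: X157, fraction: 0.01}
  "1% IPC synthase": {enzyme: X133, fraction: 0.01}
  "12.5% Ceramide synthase": {enzyme: X134, fraction: 0.125}
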