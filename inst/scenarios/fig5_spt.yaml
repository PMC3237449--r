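name: 1% SPT, 30-min pulse-chase
kind: pulse_chase
variant: dynamic
label_amount: 125
pulse_len: 30
t_end: 1000
enzyme: X157
fraction: 0.01
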