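name: acetate label bolus, wild type
kind: bolus
variant: dynamic
label_amount: 125
t_end: 1000
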