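pairing_weights:
- 0.333333333333333
- 0.333333333333333
- 0.333333333333333
univalent_bias:
- 0.5
- 0.5
- 0.5
nondisjunction_rate: 0.002
transmission_weights: []
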