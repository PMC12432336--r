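sepal_length
sepal_width,0.09
corolla_width,0.08,0.24
tube_length,-0.11,0.06,0.36
tube_width,0.10,0.14,0.16,0.20
filament_length,-0.14,0.12,0.20,0.34,0.03
anther_length,-0.03,0.15,-0.01,0.03,0.13,-0.06
ovary_length,-0.01,0.06,0.28,0.02,-0.14,0.14,-0.14
ovary_width,0.004,-0.19,0.13,0.005,0.09,0.24,-0.10,0.40
style_length,-0.09,0.03,0.44,0.46,-0.11,0.50,-0.09,0.28,0.22
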