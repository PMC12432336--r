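trait_row,trait_col,ci_low,ci_high
sepal_length,sepal_width,-0.06,0.26
sepal_length,corolla_width,0.02,0.48
sepal_length,tube_length,-0.26,0.4
sepal_length,tube_width,-0.13,0.21
sepal_length,filament_length,-0.32,-0.01
sepal_length,anther_length,-0.14,0.05
sepal_length,ovary_length,-0.08,0.25
sepal_length,ovary_width,-0.15,0.21
sepal_length,style_length,-0.25,0.52
sepal_width,corolla_width,0.01,0.44
sepal_width,tube_length,-0.17,0.27
sepal_width,tube_width,-0.05,0.33
sepal_width,filament_length,-0.11,0.3
sepal_width,anther_length,-0.02,0.33
sepal_width,ovary_length,-0.16,0.25
sepal_width,ovary_width,-0.40,0.05
sepal_width,style_length,-0.2,0.25
corolla_width,tube_length,0.15,0.54
corolla_width,tube_width,-0.09,0.37
corolla_width,filament_length,-0.04,0.39
corolla_width,anther_length,-0.26,0.08
corolla_width,ovary_length,0.07,0.47
corolla_width,ovary_width,-0.12,0.38
corolla_width,style_length,0.26,0.6
tube_length,tube_width,-0.01,0.4
tube_length,filament_length,0.09,0.54
tube_length,anther_length,-0.15,0.23
tube_length,ovary_length,-0.18,0.24
tube_length,ovary_width,-0.22,0.24
tube_length,style_length,0.24,0.63
tube_width,filament_length,-0.16,0.25
tube_width,anther_length,0.09,0.52
tube_width,ovary_length,-0.35,0.11
tube_width,ovary_width,-0.17,0.33
tube_width,style_length,-0.28,0.07
filament_length,anther_length,-0.23,0.18
filament_length,ovary_length,-0.05,0.34
filament_length,ovary_width,0.05,0.43
filament_length,style_length,0.21,0.71
anther_length,ovary_length,-0.54,-0.1
anther_length,ovary_width,-0.37,-0.04
anther_length,style_length,-0.33,0.01
ovary_length,ovary_width,0.23,0.57
ovary_length,style_length,0.04,0.47
ovary_width,style_length,-0.03,0.43
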