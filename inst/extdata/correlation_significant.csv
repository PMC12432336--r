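trait_row,trait_col
corolla_width,sepal_width
tube_length,corolla_width
tube_width,tube_length
filament_length,corolla_width
filament_length,tube_length
ovary_length,corolla_width
ovary_width,sepal_width
ovary_width,filament_length
ovary_width,ovary_length
style_length,corolla_width
style_length,tube_length
style_length,filament_length
style_length,ovary_length
style_length,ovary_width
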