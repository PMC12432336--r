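trait,code,mean_mm,sd_mm,cv_pct,cv_ci_low,cv_ci_high,pc1,pc2
sepal_length,L_sep,13.8,5.7,40.98,34.8,49.9,-0.11,0.15
sepal_width,W_sep,6.4,0.4,5.47,4.7,6.5,0.16,0.57
corolla_width,W_cor,32.8,1.8,5.58,4.8,6.6,0.66,0.28
tube_length,L_tub,30.9,2.0,6.52,5.7,7.7,0.62,0.36
tube_width,W_tub,6.7,0.6,8.74,7.6,10.4,0.09,0.56
filament_length,L_fil,29.8,1.7,5.8,5.0,6.9,0.67,-0.003
anther_length,L_ant,6.4,2.3,35.54,30.3,43.2,-0.12,0.51
ovary_length,L_ova,1.4,0.2,11.2,9.7,13.3,0.50,-0.43
ovary_width,W_ova,1.4,0.1,10.26,8.9,12.2,0.43,-0.47
style_length,L_sty,31.7,2.3,7.1,6.1,8.4,0.81,-0.07
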