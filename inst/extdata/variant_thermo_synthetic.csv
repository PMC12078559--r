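# Synthetic/derived thermal fixtures for the three photoresponsive variants.
# T_D_trans of Y_2x1x5 (50 C) and Y_3x5 (65 C) and T_D_cis of Y_2x1x5 (~3 C)
# follow the measured reference values; all T_GL values (and the remaining
# T_D values) are back-solved from the observed flow-mode temperature ranges
# and are NOT measurements. dH columns are passthrough annotations (kcal/mol,
# unavailable here).
variant_name,T_D_trans,T_D_cis,T_GL_trans,T_GL_cis,dH_trans,dH_cis
Y_2x1x5,50,3,40,3,NA,NA
Y_3x5,65,40,55,40,NA,NA
Y_1x7,80,55,75,35,NA,NA
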