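measure,group,mean_before,sd_before,mean_after,sd_after,n_animals,n_units,p_printed
sngfr_nl_min,placebo,NA,NA,NA,NA,8,13,NA
sngfr_nl_min,enalapril,4.24,1.28,2.36,1.0,5,9,0.014
sngfr_nl_min,empagliflozin,4.12,1.5,1.6,0.55,5,9,0.0006
sngfr_nl_min,enalapril_empagliflozin,6.03,3.17,2.07,0.84,5,7,0.014
aff_diam_um,placebo,12.09,1.56,11.4,1.83,5,11,NA
aff_diam_um,enalapril,12.46,1.51,12.44,1.70,2,5,NA
aff_diam_um,empagliflozin,12.35,1.32,11.19,2.55,5,7,0.044
aff_diam_um,enalapril_empagliflozin,10.42,2.03,10.97,2.00,8,14,NA
eff_diam_um,placebo,11.18,1.50,11.06,1.40,4,7,NA
eff_diam_um,enalapril,11.92,1.04,12.55,1.46,2,4,0.022
eff_diam_um,empagliflozin,12.04,1.79,12.02,1.96,4,6,NA
eff_diam_um,enalapril_empagliflozin,10.75,1.61,11.03,0.79,6,14,NA
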