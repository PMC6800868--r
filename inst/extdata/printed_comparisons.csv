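comparison_id,nrow,ncol,row_labels,col_labels,counts,printed_p,printed_sf,source
dementia_amy_vs_cr,2,2,amygdala_based;caudo_rostral,dementia_yes;dementia_no,37;3;52;31,0.0004478,4,Table 3 dementia rows; Results: demographic characteristics and dementia
dementia_amy_vs_none,2,2,amygdala_based;no_lrp,dementia_yes;dementia_no,37;3;106;74,0.000018,2,Table 3 dementia rows; Results: demographic characteristics and dementia
braak_amy_vs_cr,2,3,amygdala_based;caudo_rostral,braak_0_II;braak_III_IV;braak_V_VI,2;13;25;34;36;13,0.00000005632,4,Table 3 Braak NFT stage rows; Results: AD pathology
braak_amy_vs_none,2,3,amygdala_based;no_lrp,braak_0_II;braak_III_IV;braak_V_VI,2;13;25;54;92;34,0.0000001051,4,Table 3 Braak NFT stage rows; Results: AD pathology
braak_cr_vs_none,2,3,caudo_rostral;no_lrp,braak_0_II;braak_III_IV;braak_V_VI,34;36;13;54;92;34,0.2306,4,Table 3 Braak NFT stage rows; Results: AD pathology
cerad_amy_vs_cr,2,3,amygdala_based;caudo_rostral,cerad_none;cerad_sparse;cerad_mod_freq,1;0;39;24;9;50,0.00001861,4,Table 3 CERAD score rows; Results: AD pathology
cerad_amy_vs_none,2,3,amygdala_based;no_lrp,cerad_none;cerad_sparse;cerad_mod_freq,1;0;39;46;24;110,0.000006906,4,Table 3 CERAD score rows; Results: AD pathology
cerad_cr_vs_none,2,3,caudo_rostral;no_lrp,cerad_none;cerad_sparse;cerad_mod_freq,24;9;50;46;24;110,0.7622,4,Table 3 CERAD score rows; Results: AD pathology
apoe_amy_vs_cr,2,2,amygdala_based;caudo_rostral,apoe_e4_yes;apoe_e4_no,22;13;24;54,0.001843,4,Table 3 APOE e4 rows; Results: APOE e4 and progression patterns
apoe_amy_vs_none,2,2,amygdala_based;no_lrp,apoe_e4_yes;apoe_e4_no,22;13;44;126,0.00004611,4,Table 3 APOE e4 rows; Results: APOE e4 and progression patterns
apoe_cr_vs_none,2,2,caudo_rostral;no_lrp,apoe_e4_yes;apoe_e4_no,24;54;44;126,0.4457,4,Table 3 APOE e4 rows; Results: APOE e4 and progression patterns
spinal_cr_vs_amy,2,2,caudo_rostral;amygdala_based,spinal_lrp_present;spinal_lrp_absent,69;14;24;16,0.007219,4,Results: spinal cord pathology and progression patterns
sex_cr_vs_amy,2,2,caudo_rostral;amygdala_based,men;women,20;63;5;35,0.1576,4,Results: demographic characteristics (24% vs 12% men)
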