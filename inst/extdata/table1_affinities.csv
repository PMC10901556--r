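species,common_name,paralog,label,motif_sequence,kd_native_motif_uM,kd_native_motif_err_uM,kd_vs_human_mdm2_uM,kd_vs_human_mdm2_err_uM,kd_human_peptide_uM,kd_human_peptide_err_uM,kd_fulllength_uM,kd_fulllength_err_uM,kd_fulllength_prior_uM,kd_fulllength_prior_err_uM
Homo sapiens,human,,H. sapiens,SQETFSDLWKLLP,0.26,0.02,,,,,0.061,0.003,0.10,0.003
Lepisosteus oculatus,spotted gar,,L. oculatus,SQESFQELWNMVI,0.39,0.04,0.121,0.005,0.37,0.014,0.085,0.005,,
Anguilla anguilla,European eel,P1,A. anguilla p53TAD_P1,SQESFQELWKMMC,0.19,0.02,0.013,0.001,0.9,0.1,0.23,0.02,,
Anguilla anguilla,European eel,P2,A. anguilla p53TAD_P2,SQDETFQALWNTVT,1.2,0.2,0.77,0.02,,,0.06,0.01,,
Clupea harengus,Atlantic herring,P1,C. harengus p53TAD_P1,SQGTFDEIWASNF,2.6,0.2,1.25,0.04,1.8,0.3,0.19,0.04,,
Clupea harengus,Atlantic herring,P2,C. harengus p53TAD_P2,DSPDFEDLWNSIV,0.60,0.03,0.29,0.02,,,0.04,0.01,,
Oncorhynchus kisutch,coho salmon,P1a,O. kisutch p53TAD_P1a,GQCSFQQLWESNM,2.1,0.2,3.15,0.06,0.78,0.1,0.048,0.005,,
Oncorhynchus kisutch,coho salmon,P1b,O. kisutch p53TAD_P1b,SQGSFQQLWETNM,3.5,0.1,5.15,0.09,,,0.06,0.01,,
Oncorhynchus kisutch,coho salmon,P2,O. kisutch p53TAD_P2,SQESFEDLWKMNL,1.16,0.07,0.79,0.03,,,0.07,0.01,,
Channa argus,northern snakehead,P1,C. argus p53TAD_P1,SQDSFRELWESVV,3.3,0.4,1.1,0.3,2.1,0.2,0.10,0.03,,
Maylandia zebra,zebra mbuna,P1,M. zebra p53TAD_P1,SQDSFKELWDQLP,1.6,0.1,0.27,0.04,1.7,0.4,0.19,0.02,,
Takifugu rubripes,Japanese puffer,P1,T. rubripes p53TAD_P1,SQDTFQDLWENVA,4.5,0.8,1.7,0.1,1.1,0.2,0.47,0.03,,
Danio rerio,zebrafish,P2,D. rerio p53TAD_P2,SQEFAELWEKNL,3.6,0.3,4.33,0.05,0.79,0.05,0.049,0.008,,
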