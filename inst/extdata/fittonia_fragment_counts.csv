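marker,primer_combo,n_fragments,n_variable,n_variable_hpa,n_variable_msp
AFLP,EcoRI+AAG/MseI+CAC,53,32,NA,NA
AFLP,EcoRI+AGC/MseI+CAC,58,37,NA,NA
AFLP,EcoRI+ACA/MseI+CAG,54,23,NA,NA
AFLP,EcoRI+ACT/MseI+CAG,44,27,NA,NA
AFLP,EcoRI+ACC/MseI+CAT,94,54,NA,NA
AFLP,EcoRI+AGC/MseI+CAT,36,24,NA,NA
AFLP,EcoRI+AAC/MseI+CTA,40,13,NA,NA
AFLP,EcoRI+ACC/MseI+CTA,32,20,NA,NA
AFLP,EcoRI+ACT/MseI+CTA,53,31,NA,NA
AFLP,EcoRI+AGG/MseI+CTA,44,26,NA,NA
AFLP,EcoRI+AAC/MseI+CTT,19,4,NA,NA
AFLP,EcoRI+AGG/MseI+CTT,22,1,NA,NA
MSAP,EcoRI+ACA/HpaII-MspI+ACT,80,NA,34,14
MSAP,EcoRI+ACC/HpaII-MspI+ACT,58,NA,49,47
MSAP,EcoRI+ACT/HpaII-MspI+ACT,80,NA,60,77
MSAP,EcoRI+AGG/HpaII-MspI+ACT,60,NA,23,10
MSAP,EcoRI+AAC/HpaII-MspI+ACT,41,NA,29,20
MSAP,EcoRI+ACG/HpaII-MspI+ACT,34,NA,18,32
MSAP,EcoRI+AAC/HpaII-MspI+AAC,40,NA,19,19
MSAP,EcoRI+ACG/HpaII-MspI+AAC,30,NA,24,26
MSAP,EcoRI+AAC/HpaII-MspI+AAT,50,NA,18,22
MSAP,EcoRI+ACA/HpaII-MspI+AAT,60,NA,22,23
MSAP,EcoRI+ACG/HpaII-MspI+AAT,70,NA,45,34
MSAP,EcoRI+ACT/HpaII-MspI+AAT,64,NA,23,50
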