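code,cultivar,typeI_total,typeI_ms,typeII,typeIII,typeIV,total_amplified,total_methylated,msap_pct,full_methylated_bands,fully_methylated_pct
1,Frankie,213,101,210,155,90,668,556,83.23,300,44.91
2,Titanic,208,68,181,144,135,668,528,79.04,316,47.31
3,White Anne,207,92,213,149,99,668,553,82.78,312,46.71
4,Red Anne,213,90,211,157,87,668,545,81.59,298,44.61
5,Fortissima,207,92,202,164,95,668,553,82.78,297,44.46
6,Angel Snow,221,66,194,144,108,667,512,76.76,302,45.28
7,Red Star,204,88,216,154,94,668,552,82.63,310,46.41
8,Black Star,203,87,215,158,92,668,552,82.63,307,45.96
9,Red Vein,211,90,213,159,85,668,547,81.89,298,44.61
10,Mini-Josan,210,94,210,157,91,668,552,82.63,301,45.06
11,Leather Leaf,211,99,212,157,87,667,555,83.21,299,44.83
12,Jacmita,208,96,212,151,98,669,556,83.23,310,46.34
13,Red Angel,210,93,209,156,91,668,528,79.04,301,45.06
14,Superba,200,95,209,156,104,669,553,82.78,313,46.79
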