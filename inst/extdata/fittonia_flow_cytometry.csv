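code,cultivar,two_c_pg,two_c_sd,dna_index,one_c_mbp,ploidy
9,Red Anne,2.92,0.06,0.32,1428,2
11,Leather Leaf,2.89,0.08,0.32,1413,2
5,Fortissima,2.88,0.06,0.32,1411,2
13,Red Angel,2.86,0.04,0.31,1398,2
10,Mini Josan,2.89,0.04,0.32,1414,2
14,Superba,2.85,0.06,0.31,1395,2
12,Jacmita,2.86,0.01,0.31,1400,2
8,Black Star,2.94,0.05,0.32,1440,2
7,Red Star,2.88,0.04,0.32,1410,2
3,White Anne,2.87,0.03,0.32,1404,2
1,Frankie,2.91,0.04,0.32,1422,2
4,Red Vein,2.86,0.05,0.31,1397,2
2,Titanic,2.74,0.02,0.30,1340,2
6,Angel Snow,2.73,0.03,0.30,1336,2
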