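species,axis,eigenvalue,percent,TL,Act,AC,TIM
Danio_rerio,1,0.704,58.388,0.760,0.173,0.469,-0.416
Lima_nigrofasciata,1,0.261,62.010,0.165,0.354,0.853,0.346
Poecilia_reticulata,1,0.842,57.570,-0.593,-0.436,0.353,0.578
Xiphophorus_birchmanni,1,0.250,60.391,0.563,0.583,0.495,0.314
Xenotoca_eiseni,1,0.348,67.892,0.321,0.728,0.310,-0.521
Xiphophorus_hellerii,1,0.305,60.352,-0.192,-0.423,0.134,0.875
Xiphophorus_maculatus,1,0.706,85.349,0.237,0.383,0.644,0.619
Danio_rerio,2,0.368,30.576,0.192,0.192,0.395,0.878
Lima_nigrofasciata,2,0.149,35.352,0.233,0.540,0.057,-0.806
Poecilia_reticulata,2,0.407,27.785,0.541,0.357,0.614,0.450
Xiphophorus_birchmanni,2,0.139,34.477,0.376,0.337,-0.315,-0.804
Xenotoca_eiseni,2,0.156,30.472,0.099,0.171,0.682,0.704
Xiphophorus_hellerii,2,0.178,35.313,0.304,0.615,0.682,0.258
Xiphophorus_maculatus,2,0.112,13.561,0.333,0.513,0.283,-0.739
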