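species_a,species_b,stat,point,lo,hi
Lima_nigrofasciata,Danio_rerio,delta,0.783,0.147,1.498
Poecilia_reticulata,Danio_rerio,delta,0.258,-0.893,0.441
Poecilia_reticulata,Lima_nigrofasciata,delta,1.042,0.795,1.28
Xiphophorus_birchmanni,Danio_rerio,delta,0.790,0.095,1.405
Xiphophorus_birchmanni,Lima_nigrofasciata,delta,0.007,-0.25,0.207
Xiphophorus_birchmanni,Poecilia_reticulata,delta,1.049,0.882,1.197
Xenotoca_eiseni,Danio_rerio,delta,0.692,-0.016,1.405
Xenotoca_eiseni,Lima_nigrofasciata,delta,0.091,-0.235,0.443
Xenotoca_eiseni,Poecilia_reticulata,delta,0.951,0.651,1.232
Xenotoca_eiseni,Xiphophorus_birchmanni,delta,0.098,-0.165,0.368
Xiphophorus_hellerii,Danio_rerio,delta,0.700,0.021,1.387
Xiphophorus_hellerii,Lima_nigrofasciata,delta,0.084,-0.213,0.372
Xiphophorus_hellerii,Poecilia_reticulata,delta,0.958,0.699,1.174
Xiphophorus_hellerii,Xiphophorus_birchmanni,delta,0.090,-0.117,0.309
Xiphophorus_hellerii,Xenotoca_eiseni,delta,0.008,-0.31,0.325
Xiphophorus_maculatus,Danio_rerio,delta,0.377,-0.299,1.122
Xiphophorus_maculatus,Lima_nigrofasciata,delta,0.406,0.061,0.739
Xiphophorus_maculatus,Poecilia_reticulata,delta,0.636,0.327,0.916
Xiphophorus_maculatus,Xiphophorus_birchmanni,delta,0.413,0.135,0.715
Xiphophorus_maculatus,Xenotoca_eiseni,delta,0.315,-0.053,0.682
Xiphophorus_maculatus,Xiphophorus_hellerii,delta,0.323,-0.01,0.66
Lima_nigrofasciata,Danio_rerio,theta,63.7,32.2,90.0
Poecilia_reticulata,Danio_rerio,theta,73.1,6.5,83.1
Poecilia_reticulata,Lima_nigrofasciata,theta,75.6,37.4,89.9
Xiphophorus_birchmanni,Danio_rerio,theta,50.9,24.3,89.3
Xiphophorus_birchmanni,Lima_nigrofasciata,theta,33.9,22.7,79.7
Xiphophorus_birchmanni,Poecilia_reticulata,theta,76.6,56.9,89.9
Xenotoca_eiseni,Danio_rerio,theta,42.9,31.9,83.6
Xenotoca_eiseni,Lima_nigrofasciata,theta,66.8,15.2,89.8
Xenotoca_eiseni,Poecilia_reticulata,theta,45.6,26.1,76.7
Xenotoca_eiseni,Xiphophorus_birchmanni,theta,53.5,24.2,86.4
Xiphophorus_hellerii,Danio_rerio,theta,58.7,32.9,89.9
Xiphophorus_hellerii,Lima_nigrofasciata,theta,76.4,17.650,89.9
Xiphophorus_hellerii,Poecilia_reticulata,theta,31.6,24.7,66.3
Xiphophorus_hellerii,Xiphophorus_birchmanni,theta,89.2,33.8,89.9
Xiphophorus_hellerii,Xenotoca_eiseni,theta,38.4,4.7,84.2
Xiphophorus_maculatus,Danio_rerio,theta,73.1,26.0,89.9
Xiphophorus_maculatus,Lima_nigrofasciata,theta,20.3,9.1,74.2
Xiphophorus_maculatus,Poecilia_reticulata,theta,73.9,62.4,85.5
Xiphophorus_maculatus,Xiphophorus_birchmanni,theta,29.6,9.1,51.5
Xiphophorus_maculatus,Xenotoca_eiseni,theta,76.6,34.7,89.9
Xiphophorus_maculatus,Xiphophorus_hellerii,theta,65.1,21.0,89.9
Lima_nigrofasciata,Danio_rerio,twoK,0.567,0.279,1.144
Poecilia_reticulata,Danio_rerio,twoK,0.452,0.292,1.084
Poecilia_reticulata,Lima_nigrofasciata,twoK,0.464,0.296,0.688
Xiphophorus_birchmanni,Danio_rerio,twoK,0.365,0.216,1.112
Xiphophorus_birchmanni,Lima_nigrofasciata,twoK,0.319,0.175,0.535
Xiphophorus_birchmanni,Poecilia_reticulata,twoK,0.082,0.040,0.151
Xenotoca_eiseni,Danio_rerio,twoK,0.547,0.305,1.232
Xenotoca_eiseni,Lima_nigrofasciata,twoK,0.039,0.001,0.694
Xenotoca_eiseni,Poecilia_reticulata,twoK,0.372,0.247,0.722
Xenotoca_eiseni,Xiphophorus_birchmanni,twoK,0.194,0.098,0.500
Xiphophorus_hellerii,Danio_rerio,twoK,0.482,0.272,1.114
Xiphophorus_hellerii,Lima_nigrofasciata,twoK,0.066,0.001,0.376
Xiphophorus_hellerii,Poecilia_reticulata,twoK,0.379,0.271,0.541
Xiphophorus_hellerii,Xiphophorus_birchmanni,twoK,0.170,0.085,0.345
Xiphophorus_hellerii,Xenotoca_eiseni,twoK,0.009,0.000,0.367
Xiphophorus_maculatus,Danio_rerio,twoK,0.324,0.133,1.043
Xiphophorus_maculatus,Lima_nigrofasciata,twoK,0.097,0.007,0.631
Xiphophorus_maculatus,Poecilia_reticulata,twoK,0.440,0.157,0.764
Xiphophorus_maculatus,Xiphophorus_birchmanni,twoK,0.212,0.032,0.511
Xiphophorus_maculatus,Xenotoca_eiseni,twoK,0.067,0.003,0.653
Xiphophorus_maculatus,Xiphophorus_hellerii,twoK,0.037,0.002,0.344
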