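wavelength_nm,mua_oxy,mua_deoxy
500,11.2096,11.1721
510,10.7641,13.8021
520,13.1075,16.6013
530,21.1533,20.9048
540,28.5092,24.9512
550,23.0362,27.9951
560,17.4651,27.692
570,23.8287,24.1372
580,26.832,19.8252
590,7.71157,14.245
600,1.71368,7.86152
610,0.806844,5.05965
620,0.504894,3.48923
630,0.326996,2.6433
640,0.236972,2.26571
650,0.197327,2.0108
660,0.171613,1.73061
670,0.157693,1.49915
680,0.149132,1.29123
690,0.148081,1.10041
700,0.155615,0.962667
710,0.168433,0.879715
720,0.183387,0.825779
730,0.209051,0.764376
740,0.238983,0.725522
750,0.277464,0.75258
760,0.313775,0.894206
770,0.347919,0.78041
780,0.379899,0.719667
790,0.413995,0.56483
800,0.436303,0.40743
810,0.461878,0.383829
820,0.489582,0.370393
830,0.52048,0.370856
840,0.546025,0.369715
850,0.565149,0.369109
860,0.583197,0.371708
870,0.602307,0.379111
880,0.61607,0.38758
890,0.627693,0.402983
900,0.639312,0.417314
910,0.648621,0.430642
920,0.659432,0.44227
930,0.663811,0.453798
940,0.638175,0.467855
950,0.623188,0.471319
960,0.605166,0.472134
970,0.587264,0.470331
980,0.559127,0.466975
990,0.510561,0.463115
1000,0.462353,0.459785
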