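compound,pic50,pkd_spr,pkd_nmr,pdb_chain,rscc,clogp,delta_e
1,7.22,NC,NC,4R69 (D),0.943,5.58,-17.7
2,6.44,NC,NC,4RLS (D),0.883,4.97,-13.8
3,5.76,5.46,NC,4QO7 (A),0.958,2.86,-23.2
4,8.22,NC,NC,4R68 (B),0.979,8.07,-15.0
5,6.06,5.74,NC,4QO8 (A),0.921,6.15,13.6
6,5.3,5.3,NC,4M49 (A),0.816,3.81,-10.3
7,6.12,5.29,NC,4JNK (D),0.911,2.96,-24.9
8,<3.3,3.67,3.33,4AJE (B),0.988,2.06,-15.6
9,<3.3,2.96,3.63,,,1.63,-18.9
10,<3.3,3.55,3,4AJI (B),0.963,1.47,-19.7
11,<2.7,2.63,NC,4I8X (B),0.913,2.45,-10.4
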