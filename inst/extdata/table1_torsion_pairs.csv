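hinge_deg,goniometer_deg,software_deg
-90,-68.5,-65.6
-50,-28.5,-26.9
-40,-18.5,-15.5
-30,-8.5,-6.4
-20,1.5,3.2
-10,11.5,13.7
0,21.5,23.4
10,31.5,33.6
20,41.5,43.3
30,51.5,53.5
40,61.5,63.2
50,71.5,73.5
90,111.5,113.9
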