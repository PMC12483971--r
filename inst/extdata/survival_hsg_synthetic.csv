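"dose_Gy","value","sd","n_rep","endpoint","quality_label","schedule_label"
0,0.972103428647593,0.0483182789393385,3,"survival","","acute"
1,0.778713889284224,0.110815591827602,3,"survival","","acute"
2,0.504311331389636,0.0924352889238896,3,"survival","","acute"
3,0.404207652721782,0.0166769962378385,3,"survival","","acute"
4,0.253532108077813,0.0566571907793552,3,"survival","","acute"
5,0.151718003949654,0.0164815028689082,3,"survival","","acute"
6,0.0777769866501851,0.002796197441941,3,"survival","","acute"
7,0.0372622085329824,0.00240687465135253,3,"survival","","acute"
8,0.0135585659302849,0.00125600860833326,3,"survival","","acute"
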