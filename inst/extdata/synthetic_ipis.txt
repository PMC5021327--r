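46.69315190
68.73364368
66.70166182
79.53834963
66.98595256
37.84887628
47.38761566
40.35001632
73.18701743
47.71119218
60.79869183
50.04044135
52.70695410
29.37778967
77.03619611
32.49192234
65.92029774
27.79419034
42.84148797
60.01385647
71.51851313
73.49427796
48.35530812
29.25181355
65.48393525
29.47941758
50.30105054
51.61470594
50.59627860
42.19093148
48.68646633
73.18701458
74.71164174
28.19399185
29.72090015
58.46664735
33.19126847
78.37453929
42.95362725
36.97710433
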