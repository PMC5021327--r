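"id","type","f_max1","t_lead1","t_hc1","t_c1","t_hr1","t_tw1","f_mftf"
"synthS1","S",11.2463930808008,2.31538079306483,32.1130484021269,58.3873607311398,128.452193608508,467.098885849118,98.9144551695091
"synthFR1","FR",27.0401225611567,2.08068140316755,12.2034209496342,22.1880380902439,48.8136837985367,177.504304721951,134.64092789833
"synthFF1","FF",68.0729122716002,2.00723451701924,10.3310613400303,18.7837478909642,41.3242453601211,150.269983127713,313.523579057989
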