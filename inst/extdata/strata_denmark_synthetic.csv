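"sex","age_band","weight"
0,"[17,27)",0.075
1,"[17,27)",0.075
0,"[27,37)",0.075
1,"[27,37)",0.075
0,"[37,47)",0.075
1,"[37,47)",0.075
0,"[47,57)",0.085
1,"[47,57)",0.085
0,"[57,Inf)",0.19
1,"[57,Inf)",0.19
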