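time_h,V_feed_L,glc_feed_gL,glu_feed_mM
72,0.0005,100,50
144,0.0005,100,50
192,0.0005,100,50
240,0.0005,100,50
312,0.0005,100,50
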