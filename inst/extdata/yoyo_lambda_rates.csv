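# Measured initial per-target binding rates of YOYO-1 dye to 1-um
# stretched, surface-immobilized lambda-DNA fragments (single-molecule
# fluorescence), as shipped in yoyo_lambda_table().
conc_nM,rate_per_s
1,0.63
3,1.49
5,2.85
10,4
50,10
100,15
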