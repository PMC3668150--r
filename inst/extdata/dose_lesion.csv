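dose,lesions,source
0.1,22,B66
1,200,B65
29,6000,B65
108,24000,B66
150,30000,B65
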