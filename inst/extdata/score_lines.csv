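size,slope,intercept
0,0.0532,3.1111
1,0.0699,2.3452
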