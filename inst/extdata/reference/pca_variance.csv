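pc,eigenvalue,contribution,cumulative
1,5.126,42.714,42.714
2,1.849,15.405,58.119
3,1.691,14.094,72.212
4,1.163,9.692,81.905
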