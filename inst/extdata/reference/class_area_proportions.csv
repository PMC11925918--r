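level,y2010,y2015,y2019
lowest,7.57,6.49,6.62
low,25.24,21.39,6.18
medium,19.05,21.53,19.04
high,17.04,19.01,19.71
highest,31.11,31.58,48.44
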