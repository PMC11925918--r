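category,y2010,y2015,y2019
hazard,11.42,13.92,27.40
social_vulnerability,88.49,85.93,72.49
exposure,0.09,0.15,0.11
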