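indicator,category,weight
gdp,social_vulnerability,0.14
income,social_vulnerability,0.17
physicians,social_vulnerability,0.20
hospital_beds,social_vulnerability,0.16
older_adults,social_vulnerability,0.13
female,social_vulnerability,0.11
unemployment,social_vulnerability,0.09
ndvi,exposure,0.12
pop_density,exposure,0.32
water_resources,exposure,0.30
agricultural_practitioners,exposure,0.01
construction_practitioners,exposure,0.25
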