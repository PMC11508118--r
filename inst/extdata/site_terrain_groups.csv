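group,water_accumulation,longitudinal_convexity,cross_sectional_convexity,inundation_score
Lixisols and Luvisols,0.68,-6.98e-04,-5.35e-03,0.18
Cambisols,0.84,-8.60e-03,-5.75e-03,0.73
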