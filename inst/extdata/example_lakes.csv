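lake_id,elevation_m,area_ha
L01,2508,5.3
L02,3337,2.7
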