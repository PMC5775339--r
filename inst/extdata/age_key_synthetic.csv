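# Synthetic placeholder length-at-age cutoffs (mm): fish shorter than
# cutoff_1 are age 0+, shorter than cutoff_2 are age 1, and so on; fish
# longer than cutoff_5 are older than 4. Plausibility-shaped stand-ins,
# NOT published keys - replace from the ageing literature per species.
species,cutoff_1,cutoff_2,cutoff_3,cutoff_4,cutoff_5
polar_cod,85,125,160,190,215
capelin,80,120,145,165,185
atlantic_herring,90,130,180,220,250
atlantic_cod,110,180,250,320,380
glacier_lanternfish,35,50,60,68,74
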