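# Synthetic placeholder otolith-length to fish-length regressions.
# These coefficients are plausibility-shaped stand-ins, NOT published
# values: replace with species-specific regressions from the literature
# before drawing biological conclusions. Units: otolith length mm in,
# fish standard length mm out; valid_min/valid_max bound the otolith
# range over which the line may be applied without an extrapolation flag.
species,intercept_mm,slope,valid_min_mm,valid_max_mm
polar_cod,-6.0,45.0,0.8,5.0
capelin,14.0,38.0,0.7,4.5
atlantic_herring,8.0,40.0,0.6,5.5
atlantic_cod,4.0,22.0,1.0,10.0
glacier_lanternfish,5.0,28.0,0.5,3.0
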