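product,area_km2
agencies_niafed,71772
avhrr_landgate,60345
nasa_modis,54852
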