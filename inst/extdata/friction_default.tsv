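category	speed_kmh	override_class
forest	2	land_cover
cleared	4	land_cover
road	30	road
river	10	river
slope_s0	30	slope_s0
sources	NA	towns
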