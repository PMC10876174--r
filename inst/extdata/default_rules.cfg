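# default scoring-rule thresholds
wc.weight_g=400
wc.size_cm=10.5
wc.mitoses_20hpf=15
mwc.unfavorable_min=3
mwc.favorable_max=1
mwc.ki67_cutoff=15
ra.adult_cutoff=5
ra.adult_denominator=50
ra.pediatric_cutoff=15
ra.pediatric_denominator=20
allow_mitotic_rescale=false
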