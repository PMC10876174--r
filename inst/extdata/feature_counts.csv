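feature,count,missing
right_adrenal,37,7
left_adrenal,48,7
vascular_invasion,28,0
capsular_invasion,17,5
high_mitotic_50hpf,55,4
high_mitotic_20hpf,22,0
atypical_mitoses,31,5
necrosis,43,0
ki67_gt15,15,15
wc_benign,52,1
wc_indeterminate,17,1
wc_malignant,22,1
mwc_favorable,46,32
mwc_unfavorable,14,32
ara_benign,39,7
ara_malignant,46,7
pra_benign,47,7
pra_malignant,38,7
reticulin_intact,25,0
reticulin_altered,67,0
reticulin_qualitative,15,0
reticulin_quantitative,49,0
reticulin_both,3,0
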