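block,row_label,system,class,count
reticulin,intact,mwc,favorable,11
reticulin,intact,mwc,unfavorable,0
reticulin,intact,ara,benign,11
reticulin,intact,ara,malignant,0
reticulin,intact,pra,benign,11
reticulin,intact,pra,malignant,0
reticulin,quantitative,mwc,favorable,20
reticulin,quantitative,mwc,unfavorable,12
reticulin,quantitative,ara,benign,4
reticulin,quantitative,ara,malignant,28
reticulin,quantitative,pra,benign,5
reticulin,quantitative,pra,malignant,27
reticulin,qualitative,mwc,favorable,12
reticulin,qualitative,mwc,unfavorable,2
reticulin,qualitative,ara,benign,10
reticulin,qualitative,ara,malignant,4
reticulin,qualitative,pra,benign,13
reticulin,qualitative,pra,malignant,1
reticulin,both,mwc,favorable,2
reticulin,both,mwc,unfavorable,0
reticulin,both,ara,benign,0
reticulin,both,ara,malignant,2
reticulin,both,pra,benign,0
reticulin,both,pra,malignant,2
microscopic,gt5_per_50hpf,mwc,favorable,24
microscopic,gt5_per_50hpf,mwc,unfavorable,11
microscopic,gt5_per_50hpf,ara,benign,6
microscopic,gt5_per_50hpf,ara,malignant,29
microscopic,gt5_per_50hpf,pra,benign,10
microscopic,gt5_per_50hpf,pra,malignant,25
microscopic,gt15_per_20hpf,mwc,favorable,8
microscopic,gt15_per_20hpf,mwc,unfavorable,7
microscopic,gt15_per_20hpf,ara,benign,1
microscopic,gt15_per_20hpf,ara,malignant,14
microscopic,gt15_per_20hpf,pra,benign,1
microscopic,gt15_per_20hpf,pra,malignant,14
microscopic,necrosis,mwc,favorable,19
microscopic,necrosis,mwc,unfavorable,13
microscopic,necrosis,ara,benign,2
microscopic,necrosis,ara,malignant,30
microscopic,necrosis,pra,benign,4
microscopic,necrosis,pra,malignant,28
microscopic,vascular_invasion,mwc,favorable,7
microscopic,vascular_invasion,mwc,unfavorable,11
microscopic,vascular_invasion,ara,benign,3
microscopic,vascular_invasion,ara,malignant,15
microscopic,vascular_invasion,pra,benign,4
microscopic,vascular_invasion,pra,malignant,14
microscopic,capsular_invasion,mwc,favorable,6
microscopic,capsular_invasion,mwc,unfavorable,5
microscopic,capsular_invasion,ara,benign,2
microscopic,capsular_invasion,ara,malignant,9
microscopic,capsular_invasion,pra,benign,3
microscopic,capsular_invasion,pra,malignant,8
microscopic,ki67_gt15,mwc,favorable,4
microscopic,ki67_gt15,mwc,unfavorable,5
microscopic,ki67_gt15,ara,benign,2
microscopic,ki67_gt15,ara,malignant,7
microscopic,ki67_gt15,pra,benign,2
microscopic,ki67_gt15,pra,malignant,7
wieneke,benign,mwc,favorable,30
wieneke,benign,mwc,unfavorable,1
wieneke,benign,ara,benign,23
wieneke,benign,ara,malignant,8
wieneke,benign,pra,benign,25
wieneke,benign,pra,malignant,6
wieneke,indeterminate,mwc,favorable,7
wieneke,indeterminate,mwc,unfavorable,2
wieneke,indeterminate,ara,benign,1
wieneke,indeterminate,ara,malignant,8
wieneke,indeterminate,pra,benign,3
wieneke,indeterminate,pra,malignant,6
wieneke,malignant,mwc,favorable,8
wieneke,malignant,mwc,unfavorable,11
wieneke,malignant,ara,benign,1
wieneke,malignant,ara,malignant,18
wieneke,malignant,pra,benign,1
wieneke,malignant,pra,malignant,18
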