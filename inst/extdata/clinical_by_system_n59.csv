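variable,level,system,class,count
sex,Male,mwc,favorable,17
sex,Male,mwc,unfavorable,6
sex,Male,ara,benign,9
sex,Male,ara,malignant,14
sex,Male,pra,benign,10
sex,Male,pra,malignant,13
sex,Female,mwc,favorable,28
sex,Female,mwc,unfavorable,8
sex,Female,ara,benign,16
sex,Female,ara,malignant,20
sex,Female,pra,benign,19
sex,Female,pra,malignant,17
laterality,left,mwc,favorable,24
laterality,left,mwc,unfavorable,7
laterality,left,ara,benign,13
laterality,left,ara,malignant,18
laterality,left,pra,benign,17
laterality,left,pra,malignant,14
laterality,right,mwc,favorable,18
laterality,right,mwc,unfavorable,6
laterality,right,ara,benign,11
laterality,right,ara,malignant,13
laterality,right,pra,benign,11
laterality,right,pra,malignant,13
laterality,na,mwc,favorable,3
laterality,na,mwc,unfavorable,1
laterality,na,ara,benign,1
laterality,na,ara,malignant,3
laterality,na,pra,benign,1
laterality,na,pra,malignant,3
stage,I,mwc,favorable,29
stage,I,mwc,unfavorable,1
stage,I,ara,benign,18
stage,I,ara,malignant,12
stage,I,pra,benign,20
stage,I,pra,malignant,10
stage,II,mwc,favorable,11
stage,II,mwc,unfavorable,4
stage,II,ara,benign,4
stage,II,ara,malignant,11
stage,II,pra,benign,5
stage,II,pra,malignant,10
stage,III,mwc,favorable,4
stage,III,mwc,unfavorable,3
stage,III,ara,benign,2
stage,III,ara,malignant,5
stage,III,pra,benign,3
stage,III,pra,malignant,4
stage,IV,mwc,favorable,0
stage,IV,mwc,unfavorable,6
stage,IV,ara,benign,0
stage,IV,ara,malignant,6
stage,IV,pra,benign,0
stage,IV,pra,malignant,6
stage,na,mwc,favorable,1
stage,na,mwc,unfavorable,0
stage,na,ara,benign,1
stage,na,ara,malignant,0
stage,na,pra,benign,1
stage,na,pra,malignant,0
outcome,CR,mwc,favorable,35
outcome,CR,mwc,unfavorable,4
outcome,CR,ara,benign,24
outcome,CR,ara,malignant,15
outcome,CR,pra,benign,28
outcome,CR,pra,malignant,11
outcome,AWD,mwc,favorable,5
outcome,AWD,mwc,unfavorable,4
outcome,AWD,ara,benign,1
outcome,AWD,ara,malignant,8
outcome,AWD,pra,benign,1
outcome,AWD,pra,malignant,8
outcome,DOD,mwc,favorable,5
outcome,DOD,mwc,unfavorable,6
outcome,DOD,ara,benign,0
outcome,DOD,ara,malignant,11
outcome,DOD,pra,benign,0
outcome,DOD,pra,malignant,11
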