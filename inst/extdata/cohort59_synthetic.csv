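"case_id","age_months","sex","laterality","stage","weight_g","size_cm","mitoses_50hpf","mitoses_20hpf","atypical_mitoses","necrosis","vascular_invasion","capsular_invasion","extra_adrenal_extension","vena_cava_invasion","ki67_percent","reticulin","outcome","followup_months"
"P01","28","M","left","I","30","4.5","2","1","false","false","false","false","false","false","5","intact","AWD","30"
"P02","34","M","left","I","30","4.5","2","1","false","false","false","false","false","false","17","intact","CR","60"
"P03","40","M","left","I","30","4.5","2","1","false","false","false","false","false","false","17","intact","CR","48"
"P04","32","M","left","I","30","4.5","2","1","false","false","false","false","false","false","5","intact","CR","46"
"P05","40","M","left","I","30","4.5","2","1","false","false","false","false","false","false","5","intact","CR","52"
"P06","48","M","left","I","30","4.5","2","1","false","false","false","false","false","false","5","intact","CR","58"
"P07","56","M","left","I","30","4.5","2","1","false","false","false","false","false","false","5","intact","CR","64"
"P08","64","M","left","I","30","4.5","2","1","false","false","false","false","false","false","5","intact","CR","70"
"P09","72","M","left","I","30","4.5","2","1","false","false","false","false","false","false","5","intact","CR","76"
"P10","96","F","left","I","450","11","2","1","false","false","false","false","true","false","5","intact","CR","72"
"P11","120","F","left","I","600","12","2","1","false","false","false","false","true","true","5","intact","CR","84"
"P12","30","F","left","I","30","4.5","2","1","false","false","false","false","false","false","5","quantitative","CR","55"
"P13","36","F","left","I","30","4.5","2","1","false","false","false","false","false","false","5","quantitative","CR","58"
"P14","42","F","right","I","30","4.5","2","1","false","false","false","false","false","false","5","quantitative","CR","61"
"P15","48","F","right","I","30","4.5","2","1","false","false","false","false","false","false","5","quantitative","CR","64"
"P16","30","F","right","I","30","4.5","2","1","false","false","false","false","false","false","5","qualitative","CR","44"
"P17","40","F","right","I","30","4.5","2","1","false","false","false","false","false","false","5","qualitative","CR","48"
"P18","50","F","right","I","30","4.5","2","1","false","false","false","false","false","false","5","qualitative","CR","52"
"P19","60","F","right","II","30","4.5","2","1","false","false","false","false","false","false","5","qualitative","CR","56"
"P20","70","F","right","II","30","4.5","2","1","false","false","false","false","false","false","5","qualitative","CR","60"
"P21","80","F","right","II","30","4.5","2","1","false","false","false","false","false","false","5","qualitative","CR","64"
"P22","90","F","right","II","30","4.5","2","1","false","false","false","false","false","false","5","qualitative","CR","68"
"P23","100","F","right","III","30","4.5","2","1","false","false","false","false","false","false","5","qualitative","CR","72"
"P24","110","F","right","III","30","4.5","2","1","false","false","false","false","false","false","5","qualitative","CR","76"
"P25","120","F","","","30","4.5","2","1","false","false","false","false","false","false","5","qualitative","CR","80"
"P26","44","M","left","I","30","4.5","10","4","false","false","false","false","false","false","5","quantitative","CR","66"
"P27","52","F","left","I","30","4.5","10","4","false","false","false","false","false","false","5","qualitative","CR","70"
"P28","60","F","left","III","450","11","10","4","false","false","false","true","false","false","5","qualitative","CR","75"
"P29","109","F","left","II","30","12","10","4","true","false","false","true","false","false","20","qualitative","CR","62"
"P30","70","M","left","I","30","4.5","2","1","false","true","false","false","false","false","18","quantitative","CR","90"
"P31","76","M","left","I","30","4.5","2","1","false","true","false","false","false","false","18","quantitative","CR","95"
"P32","82","F","left","I","30","4.5","2","1","false","true","false","false","false","false","5","quantitative","CR","100"
"P33","88","F","left","I","30","4.5","2","1","false","true","false","false","false","false","5","quantitative","AWD","36"
"P34","94","F","left","I","30","4.5","2","1","false","true","false","false","false","false","5","quantitative","AWD","40"
"P35","60","M","left","I","450","11","2","1","false","true","false","false","false","false","5","quantitative","CR","105"
"P36","66","M","left","I","450","11","2","1","false","true","false","false","false","false","5","quantitative","CR","110"
"P37","72","F","left","I","450","11","2","1","false","true","false","false","false","false","5","quantitative","CR","115"
"P38","78","F","right","I","450","11","2","1","false","true","false","false","false","false","5","quantitative","AWD","44"
"P39","84","F","right","II","450","11","2","1","false","true","false","false","false","false","5","quantitative","AWD","48"
"P40","100","M","right","II","500","12","2","1","false","true","false","true","false","false","5","both","CR","120"
"P41","100","F","right","II","500","12","2","1","false","true","false","true","false","false","5","both","CR","96"
"P42","100","M","right","II","500","12","2","1","false","true","false","true","false","false","5","quantitative","CR","90"
"P43","100","M","right","II","500","12","2","1","false","true","false","true","false","false","5","quantitative","CR","86"
"P44","100","F","right","II","500","12","2","1","false","true","false","true","false","false","5","quantitative","CR","82"
"P45","100","F","","II","500","12","2","1","false","true","false","true","false","false","5","quantitative","AWD","52"
"P46","100","F","","III","500","12","2","1","false","true","false","true","false","false","5","quantitative","AWD","54"
"P47","130","M","left","I","30","4.5","2","1","false","true","true","false","false","false","25","quantitative","AWD","24"
"P48","140","F","left","II","30","4.5","2","1","true","true","true","false","false","false","10","quantitative","DOD","26"
"P49","120","M","left","II","30","4.5","2","1","true","true","true","true","false","false","20","quantitative","DOD","3"
"P50","120","M","left","II","30","4.5","2","1","true","true","true","true","false","false","20","quantitative","DOD","5"
"P51","120","F","left","III","30","4.5","2","1","true","true","true","true","false","false","20","quantitative","DOD","6"
"P52","120","F","left","III","30","4.5","2","1","true","true","true","true","false","false","8","quantitative","DOD","8"
"P53","120","F","right","III","30","4.5","2","1","true","true","true","true","false","false","8","quantitative","DOD","9"
"P54","120","F","right","IV","30","4.5","2","1","true","true","true","true","false","false","8","qualitative","AWD","16"
"P55","150","M","right","IV","200","8","40","20","true","true","true","false","false","false","8","quantitative","DOD","11"
"P56","150","M","right","IV","200","8","40","20","true","true","true","false","false","false","8","quantitative","DOD","13"
"P57","150","M","right","IV","200","8","40","20","true","true","true","false","false","false","8","quantitative","DOD","15"
"P58","150","F","right","IV","1200","15","40","20","true","true","true","false","true","true","8","quantitative","DOD","18"
"P59","150","F","","IV","1200","15","40","20","true","true","true","false","true","true","8","quantitative","DOD","22"
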